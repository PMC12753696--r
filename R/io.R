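#' Read and write cell-level cohort tables
#'
#' The on-disk format is plain CSV with one row per cell and required
#' columns `animal`, `experiment`, `group`, `cell`, `raw_green`, `raw_red`;
#' any additional columns are carried through untouched.  Ground-truth
#' allele states, when present (`green_active`, `red_active`), are written
#' to a sibling `<stem>_truth.csv` so that measurement files match what a
#' real experiment could contain.
#'
#' @param path CSV path.
#' @return `read_cell_table` returns the typed data frame;
#'   `write_cell_table` returns `path` invisibly.
#' @export
read_cell_table <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("animal", "experiment", "group", "cell", "raw_green", "raw_red")
  miss <- setdiff(need, names(tab))
  if (length(miss)) {
    stop("missing required column(s): ", paste(miss, collapse = ", "))
  }
  tab$experiment <- as.integer(tab$experiment)
  for (ch in c("raw_green", "raw_red")) {
    bad <- which(tab[[ch]] < 0)
    if (length(bad)) {
      stop("negative intensity in column ", ch, " at row ", bad[1])
    }
  }
  truth <- sub("\\.csv$", "_truth.csv", path)
  if (file.exists(truth) && !identical(truth, path)) {
    tt <- utils::read.csv(truth, stringsAsFactors = FALSE)
    key <- c("animal", "cell")
    if (all(key %in% names(tt))) {
      tab <- merge(tab, tt, by = key, all.x = TRUE, sort = FALSE)
    }
  }
  tab
}

#' @rdname read_cell_table
#' @param cells a cohort table (see [simulate_cohort()]).
#' @param ground_truth write `green_active`/`red_active` to the sibling
#'   truth file (default TRUE when the columns are present).
#' @export
write_cell_table <- function(path, cells, ground_truth = TRUE) {
  truth_cols <- intersect(c("green_active", "red_active"), names(cells))
  main <- cells[, setdiff(names(cells), truth_cols), drop = FALSE]
  utils::write.csv(main, path, row.names = FALSE)
  if (ground_truth && length(truth_cols)) {
    utils::write.csv(cells[, c("animal", "cell", truth_cols)],
                     sub("\\.csv$", "_truth.csv", path), row.names = FALSE)
  }
  invisible(path)
}

#' Read a run configuration (JSON or YAML)
#'
#' The configuration document is versioned (`schema_version` 1).  Missing
#' fields take package defaults, which are recorded in the pipeline log so
#' every defaulted decision is visible per run.
#'
#' @param path `.json`, `.yaml` or `.yml` file.
#' @return A validated `run_config` list.
#' @export
read_run_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
    json = jsonlite::read_json(path, simplifyVector = TRUE),
    yaml = ,
    yml = yaml::read_yaml(path),
    stop("config must be .json or .yaml/.yml")
  )
  as_run_config(raw)
}

#' @rdname read_run_config
#' @param config a raw config list (already parsed).
#' @export
as_run_config <- function(config) {
  if (is.null(config$schema_version)) stop("config lacks `schema_version`")
  if (!config$schema_version %in% 1) {
    stop("unrecognized schema_version: ", config$schema_version)
  }
  defaults <- list(
    schema_version = 1,
    seed = 1L,
    groups = c("wild-type", "met-2-null-like"),
    n_animals = 10L,
    n_experiments = 3L,
    n_cells = 7L,
    mean_policy = "group_experiment",
    thresholds = c(mono = 0.9, bias = 0.7),
    background_mode = "global",
    adjustment = "bonferroni",
    imaging = FALSE,
    output_dir = NULL
  )
  defaulted <- setdiff(names(defaults), names(config))
  cfg <- utils::modifyList(defaults, config[!vapply(config, is.null, TRUE)])
  if (is.list(cfg$thresholds)) cfg$thresholds <- unlist(cfg$thresholds)
  cfg$seed <- as.integer(cfg$seed)
  cfg$defaulted <- defaulted
  structure(cfg, class = "run_config")
}

#' Write a synthetic source-data workbook (fixture)
#'
#' Emits an XLSX workbook in the deposited source-data layout: one sheet per
#' figure panel, with one pair of `<group> x` / `<group> y` columns per
#' experimental group.  This is a synthetic stand-in generator for testing
#' the ingest path; it delegates the XLSX encoding to the Python `openpyxl`
#' library (R side has no writer installed), via the `python` executable on
#' the PATH.
#'
#' @param panels named list (panel name -> data frame whose columns follow
#'   the `<group> x`/`<group> y` convention).
#' @param path output `.xlsx` path.
#' @return `path`, invisibly.
#' @export
write_source_workbook <- function(panels, path) {
  if (Sys.which("python") == "") stop("python executable not found on PATH")
  tmpdir <- tempfile("wb")
  dir.create(tmpdir)
  on.exit(unlink(tmpdir, recursive = TRUE), add = TRUE)
  manifest <- file.path(tmpdir, "sheets.json")
  files <- character(0)
  for (nm in names(panels)) {
    f <- file.path(tmpdir, paste0(length(files) + 1, ".csv"))
    utils::write.csv(panels[[nm]], f, row.names = FALSE)
    files[nm] <- f
  }
  jsonlite::write_json(as.list(files), manifest, auto_unbox = TRUE)
  script <- file.path(tmpdir, "make_xlsx.py")
  writeLines(c(
    "import csv, json, sys",
    "from openpyxl import Workbook",
    "sheets = json.load(open(sys.argv[1]))",
    "wb = Workbook(); wb.remove(wb.active)",
    "for name, f in sheets.items():",
    "    ws = wb.create_sheet(title=name[:31])",
    "    with open(f) as fh:",
    "        for row in csv.reader(fh):",
    "            out = []",
    "            for v in row:",
    "                try: out.append(float(v))",
    "                except ValueError: out.append(v)",
    "            ws.append(out)",
    "wb.save(sys.argv[2])"
  ), script)
  status <- system2("python", c(script, manifest, path),
                    stdout = TRUE, stderr = TRUE)
  if (!file.exists(path)) {
    stop("workbook writer failed: ", paste(status, collapse = "\n"))
  }
  invisible(path)
}

#' Ingest a source-data workbook panel
#'
#' Locates the sheet for the named figure panel (case-insensitive substring
#' match), scans its header row for `<group> x` / `<group> y` column pairs,
#' and returns a cohort table (the x column mapped to `raw_green`, y to
#' `raw_red`) ready for [normalize_per_experiment()] and [group_noise()].
#' If a group has more than one candidate x/y pair the function refuses to
#' guess and lists the candidates.  The column mapping actually used is
#' attached as the `mapping` attribute.
#'
#' Deposited workbooks carry no animal or experiment identity per row, so
#' `animal` is synthesized from the row index and `experiment` is 1 unless
#' an `experiment` column is present.
#'
#' @param path `.xlsx` workbook.
#' @param panel panel identifier (sheet-name substring).
#' @return Cohort table data frame with attribute `mapping`.
#' @export
read_source_data_workbook <- function(path, panel) {
  sheets <- readxl::excel_sheets(path)
  hit <- grep(tolower(panel), tolower(sheets), fixed = TRUE)
  if (length(hit) == 0L) {
    stop("panel not found: \"", panel, "\"; sheets are: ",
         paste(sheets, collapse = ", "))
  }
  sheet <- sheets[hit[1]]
  tab <- as.data.frame(readxl::read_excel(path, sheet = sheet))
  hdr <- names(tab)
  xs <- grep("(^|[ ._])x$", hdr, ignore.case = TRUE, value = TRUE)
  ys <- grep("(^|[ ._])y$", hdr, ignore.case = TRUE, value = TRUE)
  stem <- function(h) trimws(sub("[ ._][xy]$", "", h, ignore.case = TRUE))
  groups <- unique(stem(xs))
  mapping <- list(sheet = sheet, pairs = list())
  out <- list()
  for (g in groups) {
    gx <- xs[stem(xs) == g]
    gy <- ys[stem(ys) == g]
    if (length(gx) != 1L || length(gy) != 1L) {
      stop("ambiguous x/y columns for group \"", g, "\": candidates ",
           paste(c(gx, gy), collapse = ", "))
    }
    x <- tab[[gx]]; y <- tab[[gy]]
    keep <- !(is.na(x) & is.na(y))
    exp_col <- grep("^experiment$", hdr, ignore.case = TRUE, value = TRUE)
    expv <- if (length(exp_col)) as.integer(tab[[exp_col[1]]][keep]) else 1L
    out[[g]] <- data.frame(
      animal = paste0(g, "_row", which(keep)),
      experiment = expv,
      group = g,
      cell = paste0("cell", which(keep)),
      raw_green = as.numeric(x[keep]),
      raw_red = as.numeric(y[keep]),
      stringsAsFactors = FALSE
    )
    mapping$pairs[[g]] <- c(x = gx, y = gy)
  }
  if (length(out) == 0L) {
    stop("no x/y column pairs found in sheet \"", sheet, "\"")
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "mapping") <- mapping
  res
}
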