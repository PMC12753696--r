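#' Allele-expression states
#' @keywords internal
mae_states <- c("mono-red", "red-biased", "biallelic", "green-biased", "mono-green")

#' Call the allele-expression state of cells
#'
#' The allele fraction `f = x / (x + y)` (green share of total reporter
#' signal) is cut into five states.  Defaults: `f >= 0.9` mono-green,
#' `0.7 <= f < 0.9` green-biased, `0.3 < f < 0.7` biallelic, and the
#' symmetric bins for red.  Monoallelic expression operates on a continuum
#' from fully monoallelic to biallelic, so the cut points are explicit
#' configuration, recorded on every result.
#'
#' @param x,y numeric vectors of (normalized) green and red values.
#' @param thresholds named numeric: `mono` (default 0.9) and `bias`
#'   (default 0.7), with `0.5 < bias < mono <= 1`.
#' @return Factor with levels mono-red, red-biased, biallelic, green-biased,
#'   mono-green; `NA` (indeterminate) where `x + y <= 0`; attributes
#'   `thresholds` and `n_indeterminate`.
#' @export
call_mae_state <- function(x, y, thresholds = c(mono = 0.9, bias = 0.7)) {
  mono <- thresholds[["mono"]]; bias <- thresholds[["bias"]]
  if (!(0.5 < bias && bias < mono && mono <= 1)) {
    stop("need 0.5 < bias < mono <= 1")
  }
  tot <- x + y
  f <- ifelse(tot > 0, x / tot, NA_real_)
  state <- rep(NA_character_, length(f))
  ok <- !is.na(f)
  state[ok & f >= mono] <- "mono-green"
  state[ok & f >= bias & f < mono] <- "green-biased"
  state[ok & f > 1 - bias & f < bias] <- "biallelic"
  state[ok & f > 1 - mono & f <= 1 - bias] <- "red-biased"
  state[ok & f <= 1 - mono] <- "mono-red"
  out <- factor(state, levels = mae_states)
  attr(out, "f") <- f
  attr(out, "thresholds") <- c(mono = mono, bias = bias)
  attr(out, "n_indeterminate") <- sum(!ok)
  out
}

#' Classify every cell of a cohort table
#'
#' @param cells normalized cohort table with columns `x`, `y`.
#' @param thresholds see [call_mae_state()].
#' @return The table with `f` and `state` columns appended; indeterminate
#'   cells (`x + y <= 0`) carry `NA` and their count is recorded in the
#'   `n_indeterminate` attribute.
#' @export
classify_cells <- function(cells, thresholds = c(mono = 0.9, bias = 0.7)) {
  if (!all(c("x", "y") %in% names(cells))) {
    stop("normalized columns `x`, `y` required (run normalize_per_experiment())")
  }
  st <- call_mae_state(cells$x, cells$y, thresholds)
  cells$f <- attr(st, "f")
  cells$state <- as.character(st)
  attr(cells, "thresholds") <- attr(st, "thresholds")
  attr(cells, "n_indeterminate") <- attr(st, "n_indeterminate")
  cells
}

#' Per-animal coherence of allele-expression states
#'
#' For each animal: the modal state among its called cells (ties broken
#' toward biallelic, then alphabetically), the coherence (fraction of cells
#' in the modal state), a `coherent` flag (coherence >= `coherent_cut`, the
#' "at least 50% of intestine cells in the same state" criterion), and a
#' `fully_mono` flag (fraction of cells monoallelic for one and the same
#' allele >= `mono_cut`, the "almost or entirely monoallelic intestine"
#' criterion).
#'
#' @param calls data frame with columns `animal` and `state` (character or
#'   factor; `NA` states are dropped with their count recorded).
#' @param coherent_cut coherence threshold for the `coherent` flag
#'   (default 0.5, boundary inclusive).
#' @param mono_cut cell-fraction threshold for `fully_mono` (default 0.9).
#' @return Data frame with one row per animal: `animal`, `n_cells`,
#'   `modal_state`, `coherence`, `coherent`, `frac_mono_green`,
#'   `frac_mono_red`, `coherent_mae` (at least `coherent_cut` of the cells
#'   share the same monoallelic state), `fully_mono`.
#' @export
animal_coherence <- function(calls, coherent_cut = 0.5, mono_cut = 0.9) {
  if (!all(c("animal", "state") %in% names(calls))) {
    stop("`calls` needs columns `animal` and `state`")
  }
  calls <- calls[!is.na(calls$state), , drop = FALSE]
  if (nrow(calls) == 0L) stop("no determinate calls")
  animals <- unique(calls$animal)
  rows <- lapply(animals, function(a) {
    st <- as.character(calls$state[calls$animal == a])
    n <- length(st)
    cnt <- table(factor(st, levels = mae_states))
    top <- max(cnt)
    cand <- names(cnt)[cnt == top]
    modal <- if ("biallelic" %in% cand) "biallelic" else sort(cand)[1]
    fg <- unname(cnt["mono-green"]) / n
    fr <- unname(cnt["mono-red"]) / n
    data.frame(animal = a, n_cells = n, modal_state = modal,
               coherence = top / n,
               coherent = (top / n) >= coherent_cut,
               frac_mono_green = fg, frac_mono_red = fr,
               coherent_mae = max(fg, fr) >= coherent_cut,
               fully_mono = max(fg, fr) >= mono_cut,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "coherent_cut") <- coherent_cut
  attr(out, "mono_cut") <- mono_cut
  out
}
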