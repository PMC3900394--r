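#' Classify a miRNA's evolutionary fate
#'
#' Screening order follows the two-stage logic of the analysis: a gene is
#' \code{"adaptive"} when its BH-adjusted MK p-value shows a significant
#' excess of divergence in the precursor (adaptive calls take precedence);
#' otherwise \code{"conservative"} when \code{K_miR/K_S < 0.5}; the rest
#' are \code{"transitional"} (between the adaptive phase and either
#' integration or death). An undefined \code{kmir_ks} (no synonymous
#' control available) is treated as not-conservative.
#'
#' @param mk_p_adjusted BH-adjusted MK p-value (precursor test).
#' @param mk_excess_divergence logical: was the divergence excess in the
#'   test class (the adaptive direction)?
#' @param kmir_ks precursor-to-synonymous divergence ratio (may be
#'   \code{NA}).
#' @param alpha_level significance level (default 0.05).
#' @param conservation_cutoff K_miR/K_S cutoff, exclusive (default 0.5).
#' @return \code{"adaptive"}, \code{"conservative"} or
#'   \code{"transitional"}.
#' @export
classify_fate <- function(mk_p_adjusted, mk_excess_divergence = TRUE,
                          kmir_ks = NA_real_, alpha_level = 0.05,
                          conservation_cutoff = 0.5) {
  if (is.na(mk_p_adjusted)) stop("mk_p_adjusted must be defined")
  if (mk_p_adjusted < alpha_level && isTRUE(mk_excess_divergence))
    return("adaptive")
  if (!is.na(kmir_ks) && kmir_ks < conservation_cutoff)
    return("conservative")
  "transitional"
}

#' Two-stage adaptive screen for one miRNA
#'
#' First stage: MK test on the precursor plus 50 bp flanks, BH-adjusted
#' across the repertoire. Second stage: re-validation with the precursor
#' alone (raw p). Both must pass for an adaptive call.
#'
#' @param p_flanked_adjusted BH-adjusted p from the flanked-precursor test.
#' @param p_precursor_alone raw p from the precursor-only test.
#' @param alpha_level significance level.
#' @return logical: does the gene pass the adaptive screen?
#' @export
adaptive_screen <- function(p_flanked_adjusted, p_precursor_alone,
                            alpha_level = 0.05) {
  p_flanked_adjusted < alpha_level & p_precursor_alone < alpha_level
}

#' Estimate the constant miRNA birth rate
#'
#' The rate is anchored on the youngest age interval, where death has had
#' the least time to act: \code{rate = n_youngest / interval_length}.
#'
#' @param n_youngest genes observed in the youngest interval.
#' @param youngest_interval_length interval length in Myr.
#' @return birth rate in genes/Myr.
#' @export
estimate_birth_rate <- function(n_youngest, youngest_interval_length) {
  if (youngest_interval_length <= 0) stop("interval length must be > 0")
  if (n_youngest < 0) stop("gene count must be >= 0")
  if (n_youngest == 0) warning("zero genes in the youngest interval; rate 0")
  n_youngest / youngest_interval_length
}

#' Build the birth-death ledger
#'
#' For each age interval, the number of newborn genes is inferred as the
#' constant birth rate times the interval length; deaths are newborns
#' minus the genes observed surviving from that interval.
#'
#' @param rate birth rate in genes/Myr.
#' @param intervals data.frame with columns \code{start}, \code{end}
#'   (Myr) and \code{survivors} (observed genes originating in the
#'   interval).
#' @return object of class \code{birth_death_ledger}: data.frame with
#'   added columns \code{newborns}, \code{deaths}, \code{death_fraction},
#'   \code{survival_fraction}, with the rate in attribute
#'   \code{birth_rate}.
#' @export
build_ledger <- function(rate, intervals) {
  stopifnot(all(c("start", "end", "survivors") %in% names(intervals)))
  if (any(intervals$end <= intervals$start))
    stop("intervals must have end > start")
  newborns <- rate * (intervals$end - intervals$start)
  if (any(intervals$survivors > newborns))
    stop("inconsistency error: survivors exceed inferred newborns in ",
         "interval(s) ",
         paste(which(intervals$survivors > newborns), collapse = ", "),
         " (birth rate likely misestimated)")
  deaths <- newborns - intervals$survivors
  out <- cbind(intervals,
               newborns = newborns,
               deaths = deaths,
               death_fraction = ifelse(newborns > 0, deaths / newborns, 0),
               survival_fraction = ifelse(newborns > 0,
                                          intervals$survivors / newborns, 1))
  attr(out, "birth_rate") <- rate
  class(out) <- c("birth_death_ledger", "data.frame")
  out
}

#' @export
print.birth_death_ledger <- function(x, ...) {
  cat("birth-death ledger (rate =", attr(x, "birth_rate"), "genes/Myr)\n")
  df <- as.data.frame(x)
  df$newborns <- round(df$newborns)
  df$deaths <- round(df$deaths)
  df$death_fraction <- sprintf("%.0f%%", 100 * df$death_fraction)
  df$survival_fraction <- sprintf("%.1f%%", 100 * df$survival_fraction)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Ledger as a JSON-ready list
#' @param ledger a \code{\link{build_ledger}} result.
#' @return plain list suitable for \code{jsonlite::write_json}.
#' @export
ledger_as_list <- function(ledger) {
  list(birth_rate = attr(ledger, "birth_rate"),
       intervals = lapply(seq_len(nrow(ledger)), function(i)
         as.list(as.data.frame(ledger)[i, ])))
}
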