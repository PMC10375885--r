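# Age-band arithmetic. Bands are closed integer intervals [start, end];
# a terminal open band ("80+") is encoded as age_end = NA and treated as
# [start, Inf) wherever widths or overlaps matter.

#' Effective upper bound of an age band
#'
#' Open ("X+") bands, stored with `age_end = NA`, are treated as unbounded.
#'
#' @param age_end integer vector of band upper bounds, `NA` for open bands.
#' @return numeric vector with `Inf` in place of `NA`.
#' @keywords internal
band_upper <- function(age_end) {
  out <- as.numeric(age_end)
  out[is.na(out)] <- Inf
  out
}

# Check a set of bands (vectors of start/end) for pairwise overlap.
# Returns TRUE if any two bands intersect.
bands_overlap <- function(age_start, age_end) {
  if (length(age_start) < 2L) return(FALSE)
  ord <- order(age_start, band_upper(age_end))
  s <- age_start[ord]
  e <- band_upper(age_end)[ord]
  any(s[-1L] <= e[-length(e)])
}

# Validate band fields: integer-valued starts >= 0, end >= start when closed.
check_band_fields <- function(age_start, age_end, where = "table") {
  if (any(is.na(age_start))) {
    abort_validation(sprintf("%s: age_start must not be missing", where))
  }
  if (any(age_start < 0)) {
    abort_validation(sprintf("%s: age_start must be >= 0", where))
  }
  if (any(age_start != floor(age_start)) ||
      any(!is.na(age_end) & age_end != floor(age_end))) {
    abort_validation(sprintf("%s: age bands must have integer bounds", where))
  }
  closed <- !is.na(age_end)
  if (any(closed & age_end < age_start)) {
    abort_validation(sprintf("%s: age_end must be >= age_start", where))
  }
  invisible(TRUE)
}

# Canonical label, e.g. "60-69" or "80+".
band_label <- function(age_start, age_end) {
  ifelse(is.na(age_end),
         paste0(age_start, "+"),
         paste0(age_start, "-", age_end))
}

#' Target bands for harmonizing a pyramid to a prevalence schedule
#'
#' Builds the band list a population table must be collapsed to before
#' prevalence rates can be applied: the schedule's own bands, preceded by
#' equally sized bands covering ages 0 to the schedule's lowest start (those
#' carry denominators but contribute zero cases).
#'
#' @param schedule a prevalence schedule (see [read_prevalence_csv()]).
#' @param below_width width in years of the filler bands below the schedule
#'   (default 10, matching decade schedules).
#' @return data frame with columns `age_start`, `age_end`.
#' @export
default_target_bands <- function(schedule, below_width = 10L) {
  sb <- unique(schedule[, c("age_start", "age_end")])
  sb <- sb[order(sb$age_start), , drop = FALSE]
  lo <- min(sb$age_start)
  below <- NULL
  if (lo > 0L) {
    starts <- seq(0L, lo - 1L, by = below_width)
    below <- data.frame(age_start = starts,
                        age_end = pmin(starts + below_width - 1L, lo - 1L))
  }
  out <- rbind(below, sb)
  rownames(out) <- NULL
  out
}

#' Collapse population counts into coarser age bands
#'
#' Sums population counts into the target bands, e.g. UN 5-year bands into the
#' 10-year bands of a prevalence schedule. Every source band must nest inside
#' exactly one target band; a source band straddling a target boundary is an
#' alignment error, because counts cannot be split without an age model.
#' Total population per (country, sex) is conserved.
#'
#' @param pop a population table (see [read_population_csv()]).
#' @param target_bands data frame with columns `age_start`, `age_end`
#'   (`NA` end = open band), pairwise non-overlapping, covering all source
#'   bands.
#' @return a population table on the target bands.
#' @export
harmonize_bands <- function(pop, target_bands) {
  check_band_fields(target_bands$age_start, target_bands$age_end, "target bands")
  if (bands_overlap(target_bands$age_start, target_bands$age_end)) {
    abort_validation("target bands overlap")
  }
  ts <- target_bands$age_start
  te <- band_upper(target_bands$age_end)

  ss <- pop$age_start
  se <- band_upper(pop$age_end)
  idx <- vapply(seq_along(ss), function(i) {
    j <- which(ts <= ss[i] & se[i] <= te)
    if (length(j) == 1L) j else NA_integer_
  }, integer(1))
  if (anyNA(idx)) {
    bad <- which(is.na(idx))[1L]
    abort_alignment(sprintf(
      "source band %s (%s, %s) does not nest in any target band",
      band_label(pop$age_start[bad], pop$age_end[bad]),
      pop$country[bad], pop$sex[bad]))
  }

  # group on the target-band index, not age_end: NA (open band) grouping keys
  # would otherwise be dropped
  key <- data.frame(country = pop$country, sex = pop$sex, band = idx)
  agg <- stats::aggregate(list(population = pop$population), by = key, FUN = sum)
  agg$age_start <- target_bands$age_start[agg$band]
  agg$age_end <- target_bands$age_end[agg$band]
  agg$band <- NULL
  agg <- agg[order(agg$country, agg$sex, agg$age_start),
             c("country", "sex", "age_start", "age_end", "population")]
  rownames(agg) <- NULL
  as_population_table(agg, year = attr(pop, "year"))
}
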