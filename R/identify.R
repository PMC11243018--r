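#' Signed mass error in parts per million
#'
#' `10^6 * (observed - reference) / reference`.
#'
#' @param observed,reference m/z values; `reference` must be positive.
#'   Vectorised.
#' @return signed ppm error.
#' @export
ppm_error <- function(observed, reference) {
  if (any(reference <= 0)) stop("reference mass must be positive")
  (observed - reference) * 1e6 / reference
}

#' Match eligible variables against a compound library
#'
#' A variable matches a reference compound when the absolute accurate-mass
#' error is strictly below `ppm_tol` and the retention-time difference is
#' within `rt_tol` minutes. Among several in-tolerance candidates the
#' smallest absolute ppm error wins, ties broken by the smallest RT
#' difference. Variables with no in-tolerance compound are reported as
#' unknowns.
#'
#' @param eligible data.frame with `variable_id`, `mz`, `rt_min` (e.g.
#'   eligible variables joined back to the feature-table metadata).
#' @param library compound library (`name`, `exact_mass`, `rt_min`).
#' @param ppm_tol ppm tolerance (strict `<`; default 5).
#' @param rt_tol retention-time tolerance in minutes (default 0.25).
#' @return list with `hits` (data.frame: `variable_id`, `compound`,
#'   `observed_mz`, `reference_mass`, `mass_error_ppm`, `delta_rt_min`) and
#'   `unknowns` (character vector of unmatched variable ids).
#' @export
match_markers <- function(eligible, library, ppm_tol = 5, rt_tol = 0.25) {
  if (nrow(library) == 0) stop("empty compound library")
  hits <- list()
  unknowns <- character(0)
  for (i in seq_len(nrow(eligible))) {
    err <- ppm_error(eligible$mz[i], library$exact_mass)
    drt <- eligible$rt_min[i] - library$rt_min
    ok <- abs(err) < ppm_tol & abs(drt) <= rt_tol
    if (!any(ok)) {
      unknowns <- c(unknowns, eligible$variable_id[i])
      next
    }
    cand <- which(ok)
    best <- cand[order(abs(err[cand]), abs(drt[cand]))][1]
    hits[[length(hits) + 1]] <- data.frame(
      variable_id = eligible$variable_id[i],
      compound = library$name[best],
      observed_mz = eligible$mz[i],
      reference_mass = library$exact_mass[best],
      mass_error_ppm = err[best],
      delta_rt_min = drt[best],
      stringsAsFactors = FALSE)
  }
  hits <- if (length(hits)) do.call(rbind, hits) else
    data.frame(variable_id = character(0), compound = character(0),
               observed_mz = numeric(0), reference_mass = numeric(0),
               mass_error_ppm = numeric(0), delta_rt_min = numeric(0),
               stringsAsFactors = FALSE)
  list(hits = hits, unknowns = unknowns)
}

#' Screening rate
#'
#' Percentage of the library found: `100 * distinct matched compounds /
#' library size`. Duplicate library entries (same name and reference mass)
#' count once in both numerator and denominator.
#'
#' @param hits hit data.frame from [match_markers()] (columns `compound`,
#'   `reference_mass`), or an integer count of distinct matched compounds.
#' @param library_size distinct-compound count of the library (> 0).
#' @return percent.
#' @export
screening_rate <- function(hits, library_size) {
  if (library_size <= 0) stop("library size must be positive")
  n <- if (is.data.frame(hits))
    nrow(unique(hits[c("compound", "reference_mass")]))
  else as.integer(hits)
  100 * n / library_size
}

#' Distinct compound count of a library
#'
#' Collapses duplicate records by (name, exact mass).
#' @param library compound library data.frame.
#' @return integer count.
#' @export
library_size <- function(library) {
  nrow(unique(library[c("name", "exact_mass")]))
}

#' Method detection limit from replicate low-level spikes
#'
#' Each replicate's concentration is back-calculated through the mean
#' intensity, `c_i = I_i * spike_level / mean(I)`, and the detection limit
#' is the one-sided 99% Student-t multiple of their standard deviation
#' (EPA MDL procedure): `LOD(ng/mL) = t[0.99, n-1] * sd(c)`. The result is
#' converted to ug/kg of sample through the extract volume and sample mass
#' (2.0 g brought to 1 mL gives a factor 0.5).
#'
#' @param replicate_intensities numeric vector (>= 2 replicates; 7 in the
#'   reference design, giving t = 3.143).
#' @param spike_level spiked concentration in ng/mL (default 20).
#' @param sample_mass sample intake in g (default 2.0).
#' @param extract_volume final extract volume in mL (default 1.0).
#' @return LOD in ug/kg.
#' @export
lod_estimate <- function(replicate_intensities, spike_level = 20,
                         sample_mass = 2.0, extract_volume = 1.0) {
  n <- length(replicate_intensities)
  if (n < 2) stop("need at least 2 replicates")
  m <- mean(replicate_intensities)
  if (m <= 0) stop("mean replicate intensity must be positive")
  conc <- replicate_intensities * spike_level / m
  lod_ng_ml <- stats::qt(0.99, n - 1) * stats::sd(conc)
  lod_ng_ml * extract_volume / sample_mass
}

#' Library hits in a blank run
#'
#' Runs a (background-only) feature table through the full screening
#' pipeline and counts library matches among its eligible variables; a
#' clean blank yields 0, confirming the absence of false positives.
#'
#' @param blank_table a [feature_table()] of a blank run.
#' @param library compound library.
#' @param ... passed to [run_pipeline()] (e.g. `seed`).
#' @return integer hit count.
#' @export
screen_blank <- function(blank_table, library = pvd_library(), ...) {
  if (nrow(blank_table$intensity) == 0) return(0L)
  rep <- run_pipeline(pipeline_config(...), table = blank_table,
                      library = library, strict = FALSE)
  nrow(rep$hits)
}
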