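#' Reference compound library
#'
#' A library is a data.frame of reference records: `no`, `name`, `category`,
#' `exact_mass` (the expected [M+H]+ m/z, Da) and `rt_min` (retention time,
#' minutes). `pvd_library()` loads the 124-compound pesticide and veterinary
#' drug library shipped with the package (69 pesticides, 55 veterinary
#' drugs, plus the two deuterated recovery internal standards flagged by
#' `is_istd`).
#'
#' @param include_istd keep the two internal-standard rows (default FALSE).
#' @return data.frame with one row per reference compound.
#' @export
pvd_library <- function(include_istd = FALSE) {
  path <- system.file("extdata", "pvd_library.csv", package = "svmscreen",
                      mustWork = TRUE)
  lib <- utils::read.csv(path, stringsAsFactors = FALSE)
  lib$is_istd <- lib$category == ""
  if (!include_istd) lib <- lib[!lib$is_istd, , drop = FALSE]
  rownames(lib) <- NULL
  lib
}

#' Screened marker-compound reference table
#'
#' The published per-marker screening results used as a regression fixture:
#' variable id, matched compound, the two VIP and weight-squared values
#' (low-vs-rest / high-vs-rest contrasts), observed m/z and retention time,
#' reported mass error (ppm) and LOD (ug/kg).
#'
#' @return data.frame with one row per confirmed marker compound.
#' @export
marker_reference <- function() {
  path <- system.file("extdata", "marker_table.tsv", package = "svmscreen",
                      mustWork = TRUE)
  utils::read.delim(path, stringsAsFactors = FALSE)
}

# category vocabulary of the screening library
.pesticide_categories <- c("insecticide", "bactericide", "herbicide",
                           "growth regulator")
.vetdrug_categories <- c("sulfamido", "nitroimidazoles", "quinolones",
                         "vermifuge", "tetracyclines", "macrolides")

#' Generate a synthetic compound library
#'
#' Draws reference records with the schema and value ranges of the screening
#' library: unique names, categories from the pesticide/veterinary-drug
#' vocabulary, exact [M+H]+ masses in 100-1000 Da and retention times in
#' 2-12 min. Masses are kept at least 0.05 Da apart so accurate-mass
#' matching at a few ppm is unambiguous. Deterministic for a fixed seed.
#'
#' @param n_pesticides,n_vetdrugs record counts (>= 0).
#' @param seed integer RNG seed.
#' @return data.frame with columns no, name, category, exact_mass, rt_min.
#' @export
generate_compound_library <- function(n_pesticides, n_vetdrugs, seed = 1L) {
  if (n_pesticides < 0 || n_vetdrugs < 0)
    stop("compound counts must be >= 0")
  n <- n_pesticides + n_vetdrugs
  out <- data.frame(no = integer(0), name = character(0),
                    category = character(0), exact_mass = numeric(0),
                    rt_min = numeric(0), stringsAsFactors = FALSE)
  if (n == 0) return(out)
  rng <- local_rng(seed)
  # jittered grid keeps pairwise mass gaps >= 0.05 Da
  slots <- sample(seq(100, 1000, length.out = max(2L * n, 20L)), n)
  mass <- sort(slots) + runif(n, -0.02, 0.02)
  data.frame(
    no = seq_len(n),
    name = c(sprintf("pesticide_%03d", seq_len(n_pesticides)),
             sprintf("vetdrug_%03d", seq_len(n_vetdrugs))),
    category = c(sample(.pesticide_categories, n_pesticides, replace = TRUE),
                 sample(.vetdrug_categories, n_vetdrugs, replace = TRUE)),
    exact_mass = sample(mass, n),
    rt_min = round(runif(n, 2, 12), 2),
    stringsAsFactors = FALSE)
}
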