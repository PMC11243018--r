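# internal helpers shared across modules

local_rng <- function(seed) {
  set.seed(as.integer(seed %% 2147483647L))
  invisible(NULL)
}

# per-stage seeds derived from one master seed, kept inside 32-bit range
derive_seed <- function(master, offset) {
  as.integer((as.numeric(master) * 1009 + offset * 9973) %% 2147483647)
}

# relative standard deviation in percent (sample sd, n-1 denominator)
rsd_pct <- function(x) {
  m <- mean(x)
  if (m == 0) return(Inf)
  100 * stats::sd(x) / abs(m)
}

# peak-table variable id dialect: M{nominal m/z}T{RT in seconds, rounded}
make_variable_id <- function(mz, rt_min) {
  sprintf("M%dT%d", round(mz), round(rt_min * 60))
}

# disambiguate clashes the way alignment software does: _2, _3, ...
uniquify_ids <- function(ids) {
  out <- ids
  dup <- duplicated(ids)
  if (any(dup)) {
    for (id in unique(ids[dup])) {
      k <- which(ids == id)
      out[k[-1]] <- paste0(id, "_", seq_along(k[-1]) + 1L)
    }
  }
  out
}

# multiplicative relative noise, truncated at -0.9 to keep intensities positive
rel_noise <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  1 + pmax(stats::rnorm(n, 0, cv), -0.9)
}
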