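# shared small synthetic fixtures, built once per test run

small_config <- function(...) {
  sim_config(n_founders = 30, n_years = 12, ...)
}

.fixture_env <- new.env(parent = emptyenv())

# memoised small dataset so several test files can share one simulation
small_dataset <- function() {
  if (is.null(.fixture_env$small)) {
    .fixture_env$small <- simulate_dataset(small_config(), seed = 101)
  }
  .fixture_env$small
}

# random pedigree with founders, full sibs, half sibs and some inbreeding
random_pedigree <- function(n = 50, n_founders = 10, seed = 1) {
  set.seed(seed)
  id <- paste0("X", seq_len(n))
  cohort <- c(rep(1L, n_founders), sample(2:5, n - n_founders, replace = TRUE))
  ped <- data.frame(id = id, dam = NA_character_, sire = NA_character_,
                    cohort = cohort, stringsAsFactors = FALSE)
  for (i in (n_founders + 1):n) {
    prev <- which(ped$cohort < ped$cohort[i])
    pr <- sample(prev, 2, replace = TRUE)
    if (pr[1] == pr[2]) pr[2] <- prev[sample.int(length(prev), 1)]
    if (pr[1] != pr[2]) {
      ped$dam[i] <- ped$id[pr[1]]
      ped$sire[i] <- ped$id[pr[2]]
    }
  }
  ped
}

# fake rn_fit carrying given chains (for detection-criterion checks)
fake_fit <- function(v_int, v_slope, centred_temps) {
  structure(list(samples = cbind(V_pe_int = v_int, V_pe_slope = v_slope),
                 centred_temps = centred_temps),
            class = "rn_fit")
}
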