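# Shared fixtures are generated in code and cached per test run.
.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, fn) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, fn(), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# A small, fast session for module-level tests.
small_config <- function(seed = 1L, ...) {
  session_config(n_neurons = 24, trials_per_stim = 12, seed = seed, ...)
}

small_session <- function(seed = 1L, mode = "dPEG_like", ...) {
  cached(paste0("small_", mode, "_", seed), function() {
    simulate_session(small_config(seed), region_mode = mode, ...)
  })
}

# Build an evoked_set directly from a response matrix and labels; used to
# test decoding logic on hand-constructed data.
fake_evoked <- function(z, stimulus, state, category,
                        outcome = NULL, is_reminder = FALSE) {
  n <- nrow(z)
  if (is.null(outcome)) {
    outcome <- ifelse(state == "active",
                      ifelse(category == "catch", "correct_reject", "hit"),
                      NA_character_)
  }
  colnames(z) <- as.character(seq_len(ncol(z)))
  events <- tibble::tibble(
    event_id = seq_len(n), trial_id = seq_len(n), state = state,
    position = 1L, category = category, stimulus = stimulus,
    snr_db = NA_real_, onset_s = seq_len(n), is_reminder = is_reminder,
    outcome = outcome
  )
  structure(
    list(z = z, events = events,
         scale = tibble::tibble(neuron = seq_len(ncol(z)), mean = 0, sd = 1),
         pupil = NULL, bins = list(bin_width = 0.02, n_baseline = 5, n_evoked = 15)),
    class = "evoked_set"
  )
}

# Fake factor-analysis fit from known parameters.
fake_fa_fit <- function(L, psi, mu = rep(0, length(psi))) {
  L <- as.matrix(L)
  structure(
    list(loadings = L, psi = psi, mu = mu, R = ncol(L),
         loglik = NA_real_, n = NA_integer_, n_iter = 0L, converged = TRUE),
    class = "fa_fit"
  )
}
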