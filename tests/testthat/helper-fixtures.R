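# Small shared fixtures, built once per test run.

# compact planted-signal dataset used by several modules
small_cfg <- function(seed = 7, coupling = 0.8, n_subjects = 8,
                      n_roi = 12, n_tr = 300, n_planted = 3, ...) {
  synth_config(n_subjects = n_subjects, n_roi = n_roi, n_tr = n_tr,
    n_planted = n_planted, coupling = coupling, seed = seed, ...)
}

small_spec <- function(n_tr = 300, tr_s = 1.5, window_tr = 30) {
  dataset_spec(tr_s = tr_s, segment_tr = n_tr, window_tr = window_tr)
}

# a tiny rating log: one rater holding `values` from the given times
rating_events <- function(times, values, rater = "r1") {
  tibble::tibble(rater_id = rater, time_s = times, value = values)
}

# mean windowed correlation of a set of edges across subjects
mean_edge_fc <- function(fc_list, edges) {
  rowMeans(sapply(fc_list, function(fc) colMeans(fc[edges, , drop = FALSE])))
}
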