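# Shared fixtures built in code: small trial sets and hand-made arrays.

# a minimal two-item trial table with explicit feature values
make_two_item_trial <- function(cue = c(0, pi), rep_ = c(0.4, -2.1),
                                target = 1L, level = "all",
                                cue_dim = "orientation") {
  df <- data.frame(trial_id = 1L, level = level, cue_dim = cue_dim,
                   set_size = 2L, target_index = target,
                   cue_1 = cue[1], cue_2 = cue[2],
                   rep_1 = rep_[1], rep_2 = rep_[2])
  class(df) <- c("swap_trials", "data.frame")
  df
}

# attach responses to a trial table without simulating
with_responses <- function(trials, response, selected = NA_integer_) {
  out <- trials
  out$response <- wrap_angle(response)
  out$ground_truth_selected <- selected
  rp <- report_features(out)
  tgt <- rp[cbind(seq_len(nrow(out)), out$target_index)]
  out$error_to_target <- circ_dist(out$response, tgt)
  class(out) <- c("swap_responses", class(trials))
  out
}

# subset a response table, keeping class and config
keep_level <- function(responses, lv) {
  sub <- responses[responses$level == lv, , drop = FALSE]
  attr(sub, "config") <- trial_config(responses)
  class(sub) <- class(responses)
  sub
}
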