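# Build a single-epoch trial table with exact correct/incorrect counts per
# stimulus class: targets are correct when withheld, foils when responded.
make_epoch_trials <- function(n_targets, n_targets_withheld,
                              n_foils, n_foils_hit,
                              isi_ms = 1000) {
  stopifnot(n_targets_withheld <= n_targets, n_foils_hit <= n_foils)
  kinds <- c(rep("target", n_targets), rep("foil", n_foils))
  responded <- c(rep(FALSE, n_targets_withheld),
                 rep(TRUE, n_targets - n_targets_withheld),
                 rep(TRUE, n_foils_hit),
                 rep(FALSE, n_foils - n_foils_hit))
  tibble::tibble(
    trial_index = seq_along(kinds),
    stimulus_kind = kinds,
    isi_ms = isi_ms,
    responded = responded
  )
}

# Independent staircase trajectory oracle: fold a pass/fail sequence through
# the +1/-1 clamped rule, returning the levels played and the final
# (post-adaptation) level.
trajectory_oracle <- function(start_level, passes, n_levels) {
  level <- start_level
  played <- integer(length(passes))
  for (i in seq_along(passes)) {
    played[i] <- level
    level <- if (passes[i]) min(level + 1L, n_levels) else max(level - 1L, 1L)
  }
  list(played = played, final = level)
}
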