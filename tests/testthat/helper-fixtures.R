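# hand-built trial rows for task-model tests; defaults make a valid trial
make_trial <- function(participant_id = "P01", session = 1L,
                       stimulation = "active", phase = "post", block = 1L,
                       trial = 1L, stimulus = "long", role = "rich",
                       response = stimulus, correct = response == stimulus,
                       rewarded = FALSE, rt_ms = 500) {
  data.frame(participant_id = participant_id, session = session,
             stimulation = stimulation, phase = phase, block = block,
             trial = trial, stimulus = stimulus, role = role,
             response = response, correct = correct, rewarded = rewarded,
             rt_ms = rt_ms, stringsAsFactors = FALSE)
}

# a complete minimal participant: both sessions, both phases, the given
# blocks of `n_per_block` trials each, alternating stimuli and response keys
make_participant <- function(participant_id = "P01", n_per_block = 20,
                             blocks = 1L, rt_ms = 500) {
  rows <- list()
  for (session in 1:2) {
    stimulation <- if (session == 1) "active" else "sham"
    for (phase in c("pre", "post")) {
      for (block in blocks) {
        stim <- rep(c("long", "short"), length.out = n_per_block)
        role <- ifelse(stim == "long", "rich", "lean")
        resp <- rep(c("long", "short"), length.out = n_per_block)
        rows[[length(rows) + 1L]] <- data.frame(
          participant_id = participant_id, session = session,
          stimulation = stimulation, phase = phase, block = block,
          trial = seq_len(n_per_block), stimulus = stim, role = role,
          response = resp, correct = resp == stim, rewarded = FALSE,
          rt_ms = rt_ms, stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}

# long cell table for contrast tests
make_cells <- function(values, ids = sprintf("P%02d", seq_len(nrow(values))),
                       cols) {
  # `values`: matrix participants x cells; `cols`: data.frame of cell factors
  out <- do.call(rbind, lapply(seq_len(nrow(values)), function(i) {
    cbind(data.frame(participant_id = ids[i], stringsAsFactors = FALSE),
          cols, rb = values[i, ])
  }))
  rownames(out) <- NULL
  out
}
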