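# shared fixtures built in code

passages <- matched_passages()

# small scored trial table with explicit z columns for aggregation tests
toy_scored <- function(n_participants = 4, conditions = c("look_negative",
                       "reappraise_negative", "look_neutral"), seed = 42) {
  set.seed(seed)
  d <- expand.grid(participant_id = seq_len(n_participants),
                   condition = conditions, trial = 1:2,
                   KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  d$sample_id <- "original"
  d$word_count <- 12L
  d$abstractness <- runif(nrow(d), 3, 4)
  d$qualifying <- TRUE
  d$affect <- sample(1:7, nrow(d), replace = TRUE)
  for (z in c("z_fps", "z_present", "z_discrepancy", "z_article", "z_long")) {
    d[[z]] <- rnorm(nrow(d))
  }
  tibble::as_tibble(d)
}
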