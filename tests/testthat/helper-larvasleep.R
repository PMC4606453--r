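# Shared fixtures and independent oracles, built in code.

# Small activity matrix with known values.
toy_activity <- function(values, bin_width = 60) {
  values <- as.matrix(values)
  activity_matrix(values, sprintf("L%02d", seq_len(nrow(values))),
                  seq(0, by = bin_width, length.out = ncol(values)),
                  bin_width)
}

# Brute-force run-length scanner for sleep bouts: walk the trace minute
# by minute, independent of the rle-based implementation.
bout_oracle <- function(v, threshold = 0) {
  starts <- integer(0); durs <- integer(0)
  in_bout <- FALSE
  for (i in seq_along(v)) {
    if (v[i] <= threshold) {
      if (!in_bout) {
        starts <- c(starts, i); durs <- c(durs, 0L); in_bout <- TRUE
      }
      durs[length(durs)] <- durs[length(durs)] + 1L
    } else in_bout <- FALSE
  }
  data.frame(start_bin = starts, duration = durs)
}

# Write an activity matrix as a long-format CSV for reader tests.
write_long_activity <- function(x, path, shuffle = FALSE, seed = 1) {
  df <- as.data.frame(x)
  if (shuffle) {
    set.seed(seed)
    df <- df[sample(nrow(df)), ]
  }
  utils::write.csv(df, path, row.names = FALSE)
  path
}

# A schedule whose "day 1" lasts exactly n_min minutes, for toy-epoch
# summaries (night fills the rest of the 24 h).
short_day_schedule <- function(n_min) {
  off <- sprintf("%02d:%02d", (9 * 60 + n_min) %/% 60,
                 (9 * 60 + n_min) %% 60)
  epoch_schedule(lights_on = "09:00", lights_off = off, start = "09:00",
                 first_day = 1L)
}

expect_same_activity <- function(a, b) {
  expect_equal(a$bin_width, b$bin_width)
  expect_equal(a$bin_start, b$bin_start)
  expect_setequal(a$larva_ids, b$larva_ids)
  expect_equal(a$values[b$larva_ids, , drop = FALSE], b$values,
               ignore_attr = TRUE)
}
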