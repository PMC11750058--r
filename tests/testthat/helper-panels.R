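# small fixtures built in code

# two sites, two years: the hand-worked toy used across design tests
toy_panel <- function() {
  panel_data(data.frame(
    unit = c("A", "A", "B", "B"),
    time = c(1L, 2L, 1L, 2L),
    y = c(1, 3, 10, 14),
    x = c(1, 2, 3, 5)))
}

# random small unbalanced panel for oracle-equivalence sweeps
random_panel <- function(n_units = 4, max_years = 6) {
  rows <- do.call(rbind, lapply(seq_len(n_units), function(i) {
    ny <- sample(2:max_years, 1)
    data.frame(unit = sprintf("U%d", i), time = seq_len(ny),
               x = rnorm(ny, i, 1), y = rnorm(ny, i, 1))
  }))
  panel_data(rows)
}

write_panel_csv <- function(df, path = tempfile(fileext = ".csv")) {
  write.csv(df, path, row.names = FALSE)
  path
}
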