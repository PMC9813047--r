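# Small in-code fixtures shared across test files.

# A two-band scheme and a tiny complete counts/population pair.
tiny_bands <- function() list(age_band(0, 49), age_band(50, Inf))

tiny_tables <- function(years = 2012:2013) {
  grid <- expand.grid(year = years, age_band = band_labels(tiny_bands()),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  counts <- cbind(grid, count = seq_len(nrow(grid)) * 10L)
  population <- cbind(grid, persons = 1e6)
  list(counts = counts, population = population)
}

# Constant-hazard mortality schedule at given interval width.
const_schedule <- function(mu, width = 1, terminal = 110) {
  age <- seq(0, terminal, by = width)
  data.frame(age = age, mx = mu)
}

write_tmp_csv <- function(df, name = "t.csv") {
  path <- tempfile(fileext = ".csv")
  utils::write.csv(df, path, row.names = FALSE)
  path
}
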