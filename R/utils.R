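# small shared helpers

monthOf <- function(dates) as.integer(format(as.Date(dates), "%m"))

# wrap an integer month offset back onto 1..12
wrapMonth <- function(m) ((as.integer(m) - 1L) %% 12L) + 1L

# mid-month anchor date used to convert a peak month into a reference day
monthAnchor <- function(month, year = 2021L) {
  as.Date(sprintf("%d-%02d-15", year, wrapMonth(month)))
}

DAYS_PER_MONTH <- 365.25 / 12

WINTER_MONTHS <- c(12L, 1L, 2L)
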