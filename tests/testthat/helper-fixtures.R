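# fixture builders shared across test files

# one-or-more-row sample table; unspecified parameters default to zero
# concentration and neutral pH
make_samples <- function(..., sample_id = NULL, village = NULL) {
  vals <- list(...)
  n <- if (length(vals)) max(lengths(vals)) else 1
  base <- list(F = 0, TA = 0, TDS = 0, Cl = 0, Na = 0, K = 0,
               SO4 = 0, NO3 = 0, Mg = 0, Ca = 0, TH = 0, pH = 7)
  df <- data.frame(sample_id = sample_id %||% paste0("s", seq_len(n)),
                   stringsAsFactors = FALSE)
  if (!is.null(village)) df$village <- village
  for (p in names(base)) df[[p]] <- vals[[p]] %||% base[[p]]
  water_samples(df, provenance = "test fixture")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# a sample sitting exactly at the WHO permissible standards
who_standard_sample <- function() {
  std <- builtin_standards("WHO")
  vals <- as.list(std$Xs)
  names(vals) <- std$parameter
  do.call(make_samples, vals)
}

# raw varimax criterion, written independently of the package internals
varimax_criterion_oracle <- function(L) {
  s <- L^2
  sum(apply(s, 2, function(col) mean(col^2) - mean(col)^2))
}

rot2 <- function(theta) {
  matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2, 2)
}
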