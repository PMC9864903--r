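`%||%` <- function(x, y) if (is.null(x)) y else x

# classed errors so callers/tests can distinguish failure modes
pd_stop <- function(class, msg, ...) {
  stop(structure(
    class = c(class, "petdosim_error", "error", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}

is_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

# trapezoid rule; x strictly increasing
trapz <- function(x, y) {
  if (length(x) < 2L) return(0)
  sum(diff(x) * (head(y, -1L) + tail(y, -1L)) / 2)
}

# write a data.frame so numeric columns round-trip bit-identically
write_csv_exact <- function(df, path) {
  out <- df
  for (j in seq_along(out)) {
    if (is.double(out[[j]])) out[[j]] <- sprintf("%.17g", out[[j]])
  }
  write.csv(out, path, row.names = FALSE, quote = TRUE)
}

canonical_organ <- function(x) tolower(trimws(x))
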