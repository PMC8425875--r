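# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
# Every stochastic operation in the package routes through this so that a
# user-level seed argument gives bitwise reproducibility without clobbering
# the session RNG.
with_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(as.integer(seed))
  force(code)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_mpinet <- function(..., class = "mpinet_error") {
  stop(structure(class = c(class, "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

assert_scalar_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_mpinet(name, " must be a single finite number",
                class = "mpinet_parameter_error")
  x
}

# Stable TSV writer: fixed column order, no quoting surprises, deterministic
# numeric formatting so identical objects produce byte-identical files.
write_tsv_stable <- function(df, path) {
  is_num <- vapply(df, is.numeric, logical(1))
  df[is_num] <- lapply(df[is_num], function(x) {
    ifelse(is.na(x), NA_character_, sprintf("%.10g", x))
  })
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = TRUE, na = "NA")
  invisible(path)
}
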