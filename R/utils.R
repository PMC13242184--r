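# Classed conditions so callers (and the CLI) can distinguish failure kinds.
stop_neffr <- function(msg, class, call = sys.call(-1)) {
  stop(structure(
    class = c(paste0("neffr_", class, "_error"), "neffr_error", "error", "condition"),
    list(message = msg, call = call)
  ))
}

# Run code with a temporary, portable RNG state; the caller's stream is untouched.
local_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion")
  force(code)
}

# Accept a file path, a connection-free text blob, or a character vector of lines.
source_lines <- function(source) {
  if (length(source) == 1L && !grepl("\n", source, fixed = TRUE) &&
      file.exists(source)) {
    out <- tryCatch(readLines(source, warn = FALSE),
                    error = function(e) stop_neffr(
                      paste0("cannot read '", source, "': ", conditionMessage(e)), "io"))
    return(out)
  }
  if (length(source) == 1L && grepl("\n", source, fixed = TRUE)) {
    return(strsplit(source, "\n", fixed = TRUE)[[1]])
  }
  if (length(source) == 1L && !file.exists(source) &&
      !grepl("[>#[:space:]]", source) && grepl("[/\\\\]|\\.[A-Za-z0-9]+$", source)) {
    stop_neffr(paste0("cannot read '", source, "': no such file"), "io")
  }
  as.character(source)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
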