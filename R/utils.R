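# shared internal helpers

#' Write a file atomically
#'
#' Runs `writer(tmp)` against a temporary path in the same directory and then
#' renames it onto `path`, so a failed run never leaves a partial output file.
#'
#' @param path Final file path.
#' @param writer A function of one argument (the temporary path) that writes
#'   the file contents.
#' @return `path`, invisibly.
#' @export
write_atomic <- function(path, writer) {
  tmp <- paste0(path, ".tmp", Sys.getpid())
  on.exit(if (file.exists(tmp)) unlink(tmp), add = TRUE)
  writer(tmp)
  if (!file.rename(tmp, path)) {
    abort(paste0("could not move temporary file onto ", path))
  }
  invisible(path)
}

# division that reports 0 (instead of NaN/Inf) when the denominator is 0,
# flagging the result as undefined
safe_div <- function(num, den) {
  if (den == 0) list(value = 0, undefined = TRUE)
  else list(value = num / den, undefined = FALSE)
}

# deterministic RNG scope: everything derives from one integer seed
local_seed <- function(seed, code) {
  withr::with_seed(seed, code)
}

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && !is.na(x) && x >= 0 && x == floor(x)
}

stopifnot_scalar_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x <= 0 || x >= 1) {
    abort(paste0("`", name, "` must be a single number in (0, 1)"))
  }
}

# all sequences strictly over the A/C/G/T alphabet?
is_acgt <- function(x) {
  !stringr::str_detect(x, "[^ACGT]")
}
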