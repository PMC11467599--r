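#' Read and write conversation threads as NDJSON
#'
#' One thread per line: `thread_id`, `platform`, optional `title`, and
#' `posts`, an array of post objects with `post_id`, `author`,
#' `timestamp`, `text`, and optional `user_description` and `followers`.
#' Serialisation is deterministic, so identical corpora produce
#' byte-identical files.
#'
#' @param threads List of thread records.
#' @param path File path.
#' @return `read_threads()` returns the list of thread records.
#' @export
write_threads <- function(threads, path) {
  lines <- vapply(threads, function(th) {
    as.character(jsonlite::toJSON(th, auto_unbox = TRUE, digits = NA,
                                  na = "null"))
  }, character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' @rdname write_threads
#' @export
read_threads <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(lines)]
  lapply(lines, function(l) jsonlite::fromJSON(l, simplifyVector = FALSE))
}

# Evaluate code under a fixed RNG seed without disturbing the caller's
# random stream.
with_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}
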