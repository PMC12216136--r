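#' SHA-256 hex digest
#'
#' @param x A raw vector or a character scalar (hashed as UTF-8 bytes).
#' @return 64-character lowercase hex digest.
#' @export
sha256_hex <- function(x) {
  if (is.character(x)) x <- charToRaw(paste(x, collapse = ""))
  if (!is.raw(x)) stop("x must be raw or character")
  sha256_hex_cpp(x)
}

GENESIS_HASH <- strrep("0", 64)

# Canonical block serialization: length-prefixed field concatenation
# ("<nchar>:<field>" per field), giving bit-exact hashing across platforms.
block_serialize <- function(index, timestamp, payload_digest, prev_hash) {
  fields <- c(as.character(index), timestamp, payload_digest, prev_hash)
  paste0(vapply(fields, function(f) sprintf("%d:%s", nchar(f, "bytes"), f), ""),
         collapse = "")
}

block_hash <- function(index, timestamp, payload_digest, prev_hash) {
  sha256_hex(block_serialize(index, timestamp, payload_digest, prev_hash))
}

#' Create an empty hash-chained ledger
#'
#' A single-writer, append-only chain of blocks. Each block stores only the
#' SHA-256 digest of its payload (raw records stay outside the ledger) plus
#' the previous block's hash, so any retroactive edit anywhere in the chain
#' is detectable by [verify_chain()]. The genesis block's `prev_hash` is 64
#' zeros. No consensus, peers or signatures: tamper-evidence at desk scale.
#'
#' @return Object of class `ledger` (empty).
#' @export
ledger_new <- function() {
  structure(list(blocks = list()), class = "ledger")
}

#' @export
print.ledger <- function(x, ...) {
  v <- verify_chain(x)
  cat("<ledger> ", length(x$blocks), " block(s); ",
      if (v$valid) "chain verifies" else paste0("INVALID at index ", v$first_bad_index),
      "\n", sep = "")
  invisible(x)
}

#' Append a record to the ledger
#'
#' Refuses to extend a chain that no longer verifies. Only the payload's
#' digest enters the block.
#'
#' @param ledger A [ledger_new()] object.
#' @param payload Raw vector or character scalar to commit.
#' @param timestamp ISO-8601 timestamp string (defaults to now, UTC).
#' @return The extended ledger; the new block is attached as
#'   `attr(, "block")`.
#' @export
append_record <- function(ledger, payload,
                          timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")) {
  stopifnot(inherits(ledger, "ledger"))
  v <- verify_chain(ledger)
  if (!v$valid)
    stop("refusing to append: chain fails verification at index ", v$first_bad_index)
  index <- length(ledger$blocks)
  prev <- if (index == 0) GENESIS_HASH else ledger$blocks[[index]]$block_hash
  digest <- sha256_hex(payload)
  blk <- list(index = index, timestamp = timestamp, payload_digest = digest,
              prev_hash = prev,
              block_hash = block_hash(index, timestamp, digest, prev))
  ledger$blocks[[index + 1]] <- blk
  attr(ledger, "block") <- blk
  ledger
}

#' Verify a ledger's hash chain
#'
#' Recomputes every block hash and every link; reports the first
#' inconsistency (0-based block index), or NA when the chain is intact.
#'
#' @param ledger A `ledger`.
#' @return List with `valid` flag and `first_bad_index`.
#' @export
verify_chain <- function(ledger) {
  stopifnot(inherits(ledger, "ledger"))
  prev <- GENESIS_HASH
  for (i in seq_along(ledger$blocks)) {
    b <- ledger$blocks[[i]]
    ok <- identical(b$index, i - 1L) || isTRUE(b$index == i - 1) # json round trip
    if (!ok || !identical(b$prev_hash, prev) ||
        !identical(block_hash(b$index, b$timestamp, b$payload_digest, b$prev_hash),
                   b$block_hash))
      return(list(valid = FALSE, first_bad_index = i - 1L))
    prev <- b$block_hash
  }
  list(valid = TRUE, first_bad_index = NA_integer_)
}

#' Read / write a ledger as JSON lines
#'
#' One block per line, UTF-8, LF endings.
#'
#' @param ledger A `ledger`.
#' @param path File path.
#' @export
write_ledger <- function(ledger, path) {
  stopifnot(inherits(ledger, "ledger"))
  lines <- vapply(ledger$blocks, function(b)
    as.character(jsonlite::toJSON(b, auto_unbox = TRUE, digits = NA)), "")
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_ledger
#' @export
read_ledger <- function(path) {
  lines <- readLines(path)
  blocks <- lapply(lines, function(l) {
    b <- jsonlite::fromJSON(l)
    b$index <- as.integer(b$index)
    b
  })
  structure(list(blocks = blocks), class = "ledger")
}
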