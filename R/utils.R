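#' @keywords internal
"_PACKAGE"

# Internal helpers shared across modules. All user-facing errors are thrown
# with a class so callers (and tests) can distinguish invalid arguments from
# state/conflict/format problems.

stop_invalid <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("ganrecon_invalid_argument", "ganrecon_error")))
}

stop_conflict <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("ganrecon_conflict", "ganrecon_error")))
}

stop_not_found <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("ganrecon_not_found", "ganrecon_error")))
}

stop_state <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("ganrecon_state_error", "ganrecon_error")))
}

stop_format <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("ganrecon_format_error", "ganrecon_error")))
}

assert_scalar_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_invalid("`%s` must be a single finite number", name)
  x
}

assert_count <- function(x, name, min = 1L) {
  assert_scalar_number(x, name)
  if (x < min || x != floor(x))
    stop_invalid("`%s` must be an integer >= %d (got %s)", name, min, format(x))
  as.integer(x)
}

assert_scalar_number_or_inf <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x <= 0)
    stop_invalid("`%s` must be a positive number (or Inf)", name)
  x
}

assert_flag <- function(x, name) {
  if (!is.logical(x) || length(x) != 1L || is.na(x))
    stop_invalid("`%s` must be TRUE or FALSE", name)
  x
}

assert_string <- function(x, name) {
  if (!is.character(x) || length(x) != 1L || is.na(x) || !nzchar(x))
    stop_invalid("`%s` must be a nonempty string", name)
  x
}

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's
# global RNG state. Every stochastic operation in the package runs through
# this, so generation/training are pure functions of (arguments, seed).
with_rng <- function(seed, expr) {
  seed <- assert_count(seed, "seed", min = 0L)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Deterministic sub-seed derivation, kept below 2^31 - 1.
derive_seed <- function(seed, offset) {
  as.integer((as.double(seed) * 48271 + as.double(offset)) %% 2147483647)
}

# ---- tile helpers ---------------------------------------------------------

# A "tile" is an H x W x 3 numeric array on the 0-255 scale, with optional
# attributes: label, row, col (0-based top-left corner), source_id.

assert_tile <- function(tile, name = "tile") {
  if (!is.array(tile) || length(dim(tile)) != 3L)
    stop_invalid("`%s` must be an H x W x C array", name)
  if (dim(tile)[3] != 3L)
    stop_invalid("`%s` must have exactly 3 channels (got %d); no silent conversion",
                 name, dim(tile)[3])
  tile
}

tile_label <- function(tile) attr(tile, "label", exact = TRUE)

set_tile_meta <- function(tile, label = NULL, row = NULL, col = NULL,
                          source_id = NULL) {
  if (!is.null(label)) attr(tile, "label") <- label
  if (!is.null(row)) attr(tile, "row") <- row
  if (!is.null(col)) attr(tile, "col") <- col
  if (!is.null(source_id)) attr(tile, "source_id") <- source_id
  tile
}

# dim-preserving clamps (pmax(0, x) would take attributes from the scalar)
clamp01 <- function(x) {
  x[x < 0] <- 0
  x[x > 1] <- 1
  x
}
clamp255 <- function(x) {
  x[x < 0] <- 0
  x[x > 255] <- 255
  x
}
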