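#' @keywords internal
"_PACKAGE"

## Internal helpers shared across modules.

# Run `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's stream afterwards. `seed = NULL` leaves the stream untouched.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single integer", call. = FALSE)
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Deterministic sub-seed for a named stage, kept below 2^31.
derive_seed <- function(seed, stage) {
  if (is.null(seed)) return(NULL)
  h <- poly_hash(paste0(stage, ":", as.integer(seed)))
  as.integer(h %% 2147483587) + 1L
}

# Polynomial rolling hash of strings, mod 2^31 - 1. Used for sub-seed
# derivation and manifest parameter hashes; stable across platforms.
poly_hash <- function(x) {
  bytes <- utf8ToInt(enc2utf8(paste(x, collapse = "\x1f")))
  h <- 0
  for (b in bytes) h <- (h * 131 + b) %% 2147483647
  h
}

# Validate an expression matrix: numeric, dimnames, unique ids.
check_expr <- function(x, layer = NULL, arg = "x") {
  if (!is.matrix(x) || !is.numeric(x)) {
    stop(sprintf("`%s` must be a numeric matrix (genes x samples)", arg), call. = FALSE)
  }
  if (is.null(rownames(x)) || is.null(colnames(x))) {
    stop(sprintf("`%s` must have gene rownames and sample colnames", arg), call. = FALSE)
  }
  dup_g <- unique(rownames(x)[duplicated(rownames(x))])
  if (length(dup_g)) {
    stop("duplicated gene id(s): ", paste(dup_g, collapse = ", "), call. = FALSE)
  }
  dup_s <- unique(colnames(x)[duplicated(colnames(x))])
  if (length(dup_s)) {
    stop("duplicated sample id(s): ", paste(dup_s, collapse = ", "), call. = FALSE)
  }
  if (!is.null(layer)) {
    lay <- attr(x, "layer")
    if (!is.null(lay) && !identical(lay, layer)) {
      stop(sprintf("`%s` must be a %s-layer matrix, got %s", arg, layer, lay), call. = FALSE)
    }
  }
  invisible(x)
}

expr_layer <- function(x) {
  lay <- attr(x, "layer")
  if (is.null(lay)) "counts" else lay
}

`expr_layer<-` <- function(x, value) {
  attr(x, "layer") <- value
  x
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two label vectors, used throughout the
#' package to compare clusterings with each other and with planted truth.
#' Thin wrapper around [mclust::adjustedRandIndex()].
#'
#' @param a,b label vectors of equal length (any atomic type).
#' @return A single number in \[-1, 1\]; 1 means identical partitions.
#' @export
adjusted_rand <- function(a, b) {
  if (length(a) != length(b)) stop("label vectors must have equal length", call. = FALSE)
  mclust::adjustedRandIndex(a, b)
}
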