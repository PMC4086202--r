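# Internal helpers shared across modules.

# Round half away from zero (base round() is banker's rounding; edge counts
# at a fixed cost must not depend on the parity of the nearest integer).
round_half_up <- function(x) {
  sign(x) * floor(abs(x) + 0.5)
}

# Canonical unordered node-pair: node1 < node2 in C-locale string order.
# All edge tables key on names, never indices.
canonical_edge <- function(a, b) {
  swap <- a > b
  n1 <- ifelse(swap, b, a)
  n2 <- ifelse(swap, a, b)
  list(node1 = n1, node2 = n2)
}

edge_key <- function(a, b) {
  ce <- canonical_edge(a, b)
  paste(ce$node1, ce$node2, sep = "\r")
}

# Deterministic per-subject seed derived from a master seed: a Weyl-style
# integer mix keeping the result a valid positive 32-bit R seed.
derive_seed <- function(master, index) {
  stopifnot(is.numeric(master), is.numeric(index))
  ((as.double(master) %% 2147483647) * 48271 + as.double(index) * 69621) %%
    2147483629 + 1
}

# Evaluate `expr` under a local RNG seed, restoring the caller's RNG state.
with_local_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(seed)
  }
  force(expr)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Low-overhead tibble construction for hot loops (no recycling or name
# repair; all columns must already be full-length and named).
quick_tbl <- function(...) {
  cols <- lapply(list(...), unname)
  tibble::new_tibble(cols, nrow = length(cols[[1]]))
}
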