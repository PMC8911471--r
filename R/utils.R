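# Small shared helpers: deterministic seed derivation and structure lookup.

# Derive a child seed from a parent seed and a string label, so that every
# structure/observer/fraction consumes an independent, reproducible stream
# and adding one structure never perturbs the others.  Plain 32-bit integer
# hashing (FNV-style) keeps results identical across platforms.
derive_seed <- function(seed, ...) {
  label <- paste(c(as.character(seed), unlist(list(...))), collapse = "/")
  # multiply-add hash kept below 2^31 so every product is exact in doubles
  h <- 2166136261 %% 2147483647
  for (b in utf8ToInt(label)) {
    h <- (h * 69069 + b) %% 2147483647
  }
  as.integer(h %% 2147483629 + 1)
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# Case-insensitive structure lookup with an optional alias map, because
# observer exports name the same organ "Bladder", "bladder_full", ...
# `aliases` maps canonical name -> character vector of accepted names.
find_structure <- function(structures, name, aliases = NULL) {
  nms <- names(structures)
  accepted <- c(name, if (!is.null(aliases)) aliases[[name]])
  hit <- which(tolower(nms) %in% tolower(accepted))
  if (length(hit) == 0)
    stop("structure '", name, "' not found; available: ",
         paste(nms, collapse = ", "))
  structures[[hit[1]]]
}

`%||%` <- function(a, b) if (is.null(a)) b else a
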