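# internal helpers shared across modules

# run `expr` under a fixed RNG state, restoring the caller's state afterwards
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
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
    }, add = TRUE)
    set.seed(seed)
  }
  force(expr)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

is_count <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 0 && x == round(x)
is_scalar_num <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

# cumulative arc length of a polyline given as an n x 3 matrix (rows = nodes)
polyline_arclength <- function(nodes) {
  n <- nrow(nodes)
  if (n < 2L) return(0)
  d <- sqrt(rowSums((nodes[-1L, , drop = FALSE] - nodes[-n, , drop = FALSE])^2))
  c(0, cumsum(d))
}

# point on a base->tip polyline at arc length `s` from the base
polyline_point_at <- function(nodes, s) {
  cum <- polyline_arclength(nodes)
  total <- cum[length(cum)]
  s <- min(max(s, 0), total)
  i <- findInterval(s, cum, rightmost.closed = TRUE)
  if (i >= nrow(nodes)) return(nodes[nrow(nodes), ])
  seg <- cum[i + 1L] - cum[i]
  f <- if (seg > 0) (s - cum[i]) / seg else 0
  nodes[i, ] + f * (nodes[i + 1L, ] - nodes[i, ])
}

# truncate a base->tip polyline to the leading `s` of arc length, interpolating
# the cut node; returns NULL when s <= 0
polyline_truncate <- function(nodes, s) {
  cum <- polyline_arclength(nodes)
  total <- cum[length(cum)]
  if (s <= 0) return(NULL)
  if (s >= total) return(nodes)
  i <- findInterval(s, cum, rightmost.closed = TRUE)  # s falls in segment i
  seg <- cum[i + 1L] - cum[i]
  f <- if (seg > 0) (s - cum[i]) / seg else 0
  cut <- nodes[i, ] + f * (nodes[i + 1L, ] - nodes[i, ])
  kept <- nodes[seq_len(i), , drop = FALSE]
  if (f > 1e-12) kept <- rbind(kept, cut)
  if (nrow(kept) < 2L) kept <- rbind(nodes[1L, , drop = FALSE], cut)
  kept
}

# 3D connected-component labelling of a logical array, 26-connectivity.
# Returns a list(coords = m x 3 1-based arr.ind matrix, label = integer m).
label_components_3d <- function(mask) {
  stopifnot(is.logical(mask) || is.numeric(mask))
  dm <- dim(mask)
  co <- which(mask != 0)
  m <- length(co)
  if (m == 0L) return(list(coords = matrix(integer(), 0, 3), label = integer()))
  coords <- arrayInd(co, dm)
  key <- co  # linear index doubles as hash key
  off <- as.matrix(expand.grid(dz = -1:1, dy = -1:1, dx = -1:1))
  off <- off[rowSums(abs(off)) > 0, , drop = FALSE]
  # half the offsets suffice for an undirected graph
  off <- off[seq_len(nrow(off) / 2), , drop = FALSE]
  edges <- vector("list", nrow(off))
  for (k in seq_len(nrow(off))) {
    nz <- coords[, 1] + off[k, 1]; ny <- coords[, 2] + off[k, 2]; nx <- coords[, 3] + off[k, 3]
    ok <- nz >= 1 & nz <= dm[1] & ny >= 1 & ny <= dm[2] & nx >= 1 & nx <= dm[3]
    nkey <- (nx - 1) * (dm[1] * dm[2]) + (ny - 1) * dm[1] + nz
    j <- rep(NA_integer_, m)
    j[ok] <- match(nkey[ok], key)
    hit <- which(!is.na(j))
    if (length(hit)) edges[[k]] <- cbind(hit, j[hit])
  }
  edges <- do.call(rbind, edges)
  if (is.null(edges) || nrow(edges) == 0L) {
    label <- seq_len(m)
  } else {
    g <- igraph::make_graph(edges = as.vector(t(edges)), n = m, directed = FALSE)
    label <- igraph::components(g)$membership
  }
  list(coords = coords, label = as.integer(label))
}
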