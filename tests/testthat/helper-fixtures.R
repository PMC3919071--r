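# Shared fixtures (built in code, cached per test run) and independent
# oracles used to cross-check the compiled shortest-path engine and the
# signed-rank test.

.fixtures <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  if (is.null(.fixtures[[key]])) .fixtures[[key]] <- builder()
  .fixtures[[key]]
}

# Small one-region phantom + subjects + template, enough structure for
# kernel/meta tests without noticeable runtime.
tiny_dataset <- function() {
  cached("tiny", function() {
    spec <- phantom_spec(grid_shape = c(12, 12, 12), voxel_size_mm = 2,
                         regions = list(
                           list(label = 1, shape = "sphere",
                                center = c(4, 6, 6), radius = 3,
                                tissue = 0.9),
                           list(label = 2, shape = "sphere",
                                center = c(10, 6, 6), radius = 2,
                                tissue = 0.9)))
    phantom <- make_phantom(spec)
    vols <- simulate_subjects(phantom,
                              simulation_params(n_subjects = 16,
                                                smoothing_sigma_mm = 2,
                                                seed = 42))
    list(phantom = phantom, volumes = vols,
         template = neighbor_correlations(vols))
  })
}

# Two-region layout for a 16^3 validation grid (one effect region per
# split).
small_regions <- function() {
  list(list(label = 1, shape = "sphere", center = c(5, 8, 8), radius = 3,
            tissue = 0.9),
       list(label = 2, shape = "sphere", center = c(12, 8, 8), radius = 3,
            tissue = 0.9))
}

# Template with arbitrary correlations/tissue for oracle comparisons.
random_template <- function(shape, seed, rho_range = c(-0.2, 1),
                            tissue_range = c(0, 1)) {
  set.seed(seed)
  rho <- array(runif(prod(shape) * 13, rho_range[1], rho_range[2]),
               c(shape, 13))
  tissue <- volume_grid(array(runif(prod(shape), tissue_range[1],
                                    tissue_range[2]), shape),
                        voxel_size = c(2, 2, 2))
  correlation_template(rho, tissue)
}

# Independent shortest-path oracle: iterative whole-array edge relaxation
# (Bellman-Ford style) over the 26 neighborhood directions until a fixed
# point. No priority queue, no frontier logic shared with the compiled
# path; edge correlations are resolved from the 13-map storage with
# query_correlation semantics (stored at the source voxel for canonical
# offsets, at the displaced voxel otherwise) and attenuated with the
# exported attenuate().
oracle_distances <- function(template, seed, config) {
  d <- dim(template$rho)[1:3]
  no <- neighbor_offsets()
  tis <- template$tissue_prob$data

  # out[w] = x[w - o] where in range, else `fill`
  shift_by <- function(x, o, fill = Inf) {
    x <- array(x, d)  # guard against dropped singleton dimensions
    out <- array(fill, d)
    lo <- pmax(1, 1 + o); hi <- pmin(d, d + o)
    if (any(lo > hi)) return(out)  # offset exceeds a thin dimension
    dst <- lapply(1:3, function(ax) lo[ax]:hi[ax])
    src <- lapply(1:3, function(ax) dst[[ax]] - o[ax])
    out[dst[[1]], dst[[2]], dst[[3]]] <- x[src[[1]], src[[2]], src[[3]]]
    out
  }

  # per-direction edge weight array, indexed by the source voxel
  weights <- lapply(seq_len(26), function(r) {
    o <- no$offsets[r, ]
    dreal <- sqrt(sum((o * template$voxel_size)^2))
    if (config$alpha == 0) return(array(dreal, d))
    h <- no$half_index[r]
    rho <- if (no$is_half[r]) array(template$rho[, , , h], d) else
      shift_by(template$rho[, , , h], -o, fill = NA)
    p_nb <- shift_by(tis, -o, fill = NA)
    rho <- attenuate(rho, pmin(tis, p_nb), config$tissue_threshold)
    safe <- pmin(pmax(rho, 1e-300), 1)  # log argument; invalids masked below
    w <- ifelse(!is.na(rho) & rho > 0,
                sqrt((1 - config$alpha) * dreal^2 +
                     config$alpha * 2 * config$sigma_mm^2 *
                       log(1 / safe)),
                Inf)
    # neighbor out of grid: no edge
    w[is.na(p_nb)] <- NA  # placeholder, masked by shift fill below
    w
  })

  dist <- array(Inf, d)
  dist[seed[1], seed[2], seed[3]] <- 0
  repeat {
    changed <- FALSE
    for (r in seq_len(26)) {
      o <- no$offsets[r, ]
      cand <- shift_by(dist + ifelse(is.na(weights[[r]]), Inf,
                                     weights[[r]]), o)
      cand[cand > config$cutoff_mm] <- Inf
      upd <- cand < dist - 1e-12
      if (any(upd)) {
        dist[upd] <- cand[upd]
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  dist
}

# Exact two-sided signed-rank p by full 2^n enumeration of sign patterns.
enum_signrank_p <- function(x, y) {
  d <- (x - y)
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) return(1)
  r <- rank(abs(d))
  w <- sum(r[d > 0])
  ws <- vapply(0:(2^n - 1), function(m)
    sum(r[bitwAnd(m, 2^(seq_len(n) - 1)) > 0]), numeric(1))
  min(1, 2 * min(mean(ws >= w), mean(ws <= w)))
}
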