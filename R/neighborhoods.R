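#' Moore neighbourhood of cells on the integer lattice
#'
#' Two cells are lattice neighbours when their integer coordinates differ by
#' at most one in every axis (up to 26 neighbours: 8 in plane, 9 above, 9
#' below).  Only neighbouring cells are tested for particle-level adhesion.
#'
#' @param lattice_coords integer matrix with one row per cell (3 columns).
#' @return two-column integer matrix of cell-index pairs (a < b).
#' @export
moore_cell_neighbors <- function(lattice_coords) {
  lattice_coords <- as.matrix(lattice_coords)
  if (anyDuplicated(lattice_coords))
    stop("duplicate lattice coordinates")
  n <- nrow(lattice_coords)
  out <- list()
  for (a in seq_len(n)) {
    if (a < n) {
      db <- abs(sweep(lattice_coords[(a + 1):n, , drop = FALSE], 2,
                      lattice_coords[a, ], `-`))
      hit <- which(apply(db, 1, max) <= 1)
      if (length(hit)) out[[length(out) + 1]] <- cbind(a, a + hit)
    }
  }
  if (!length(out)) return(matrix(integer(0), 0, 2))
  m <- do.call(rbind, out)
  colnames(m) <- c("a", "b")
  m
}

# Candidate external particle pairs: all membrane-particle pairs of
# Moore-neighbour cells, minus excluded type pairs and lumen-target pairs.
# Cached on the population (invalidated when exclusions change).
.link_candidates <- function(pop) {
  if (!is.null(pop$cand)) return(pop)
  lat <- do.call(rbind, lapply(pop$cells, `[[`, "lattice"))
  pairs <- moore_cell_neighbors(lat)
  types <- cell_types(pop)
  ca <- cb <- list()
  for (k in seq_len(nrow(pairs))) {
    a <- pairs[k, 1]; b <- pairs[k, 2]
    if (.types_broken(pop, types[a], types[b])) next
    ia <- .cell_particles(pop, a); ib <- .cell_particles(pop, b)
    g <- expand.grid(ia = ia, ib = ib)
    ca[[length(ca) + 1]] <- g$ia
    cb[[length(cb) + 1]] <- g$ib
  }
  pop$cand <- list(a = as.integer(unlist(ca)), b = as.integer(unlist(cb)))
  if (!is.null(pop$lumen)) {
    t <- logical(nrow(pop$pos)); t[pop$lumen$targets] <- TRUE
    drop <- t[pop$cand$a] & t[pop$cand$b]
    pop$cand$a <- pop$cand$a[!drop]
    pop$cand$b <- pop$cand$b[!drop]
  }
  pop$cell_pairs <- pairs
  pop
}

.types_broken <- function(pop, ta, tb) {
  paste(sort(c(ta, tb)), collapse = ":") %in% pop$broken_types
}

#' Recompute external adhesion links
#'
#' For every Moore-neighbour cell pair, particle pairs closer than
#' `params$adhesion_cutoff` are linked, nearest first, with at most
#' `params$max_links` links per particle.  Pairs whose cell types have been
#' separated with [break_adhesion()], and pairs of lumen target particles
#' after [open_lumen()], are never linked again.
#'
#' @param pop a `sem_population`.
#' @param params a [sim_params()].
#' @param method `"gated"` uses the compiled nearest-first search over
#'   Moore-gated candidates; `"brute"` is a plain-R all-pairs reference
#'   implementation used for validation.
#' @return the population with refreshed `links`.
#' @export
external_particle_neighbors <- function(pop, params = sim_params(),
                                        method = c("gated", "brute")) {
  method <- match.arg(method)
  pop <- .link_candidates(pop)
  if (length(pop$cand$a) == 0) {
    pop$links <- list(a = integer(0), b = integer(0))
    return(pop)
  }
  if (method == "gated") {
    res <- cpp_pair_links(pop$pos, pop$cand$a, pop$cand$b,
                          params$adhesion_cutoff, params$max_links)
    pop$links <- list(a = as.integer(res$a), b = as.integer(res$b))
  } else {
    a <- pop$cand$a; b <- pop$cand$b
    d2 <- rowSums((pop$pos[a, , drop = FALSE] - pop$pos[b, , drop = FALSE])^2)
    keep <- which(d2 < params$adhesion_cutoff^2)
    keep <- keep[order(d2[keep], keep)]
    cnt <- integer(nrow(pop$pos))
    la <- lb <- integer(0)
    for (k in keep) {
      if (cnt[a[k]] < params$max_links && cnt[b[k]] < params$max_links) {
        la <- c(la, a[k]); lb <- c(lb, b[k])
        cnt[a[k]] <- cnt[a[k]] + 1L; cnt[b[k]] <- cnt[b[k]] + 1L
      }
    }
    pop$links <- list(a = la, b = lb)
  }
  pop
}

#' Break all adhesion between two cell types
#'
#' Deactivates every external link between cells of the two types and
#' excludes such pairs from all later link refreshes, leaving each tissue's
#' own mechanics untouched.
#'
#' @param pop a `sem_population`.
#' @param type_a,type_b cell type names.
#' @return the modified population.
#' @export
break_adhesion <- function(pop, type_a, type_b) {
  types <- cell_types(pop)
  if (!type_a %in% types) stop("unknown cell type: ", type_a)
  if (!type_b %in% types) stop("unknown cell type: ", type_b)
  key <- paste(sort(c(type_a, type_b)), collapse = ":")
  pop$broken_types <- union(pop$broken_types, key)
  pop$cand <- NULL  # invalidate candidate cache
  if (length(pop$links$a)) {
    ta <- types[pop$cell_of[pop$links$a]]
    tb <- types[pop$cell_of[pop$links$b]]
    drop <- mapply(function(x, y) paste(sort(c(x, y)), collapse = ":"),
                   ta, tb) == key
    pop$links$a <- pop$links$a[!drop]
    pop$links$b <- pop$links$b[!drop]
  }
  pop
}

#' Export the adhesion graph
#' @param pop a `sem_population`.
#' @param t optional step stamp recorded in the table.
#' @return data.frame with one row per active link.
#' @export
adhesion_graph <- function(pop, t = NA_integer_) {
  data.frame(cell_a = pop$cell_of[pop$links$a], particle_a = pop$links$a,
             cell_b = pop$cell_of[pop$links$b], particle_b = pop$links$b,
             active = TRUE, t = t)
}
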