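#' Multi-restart Louvain community detection
#'
#' Runs igraph's Louvain heuristic under `restarts` fixed RNG seeds and
#' returns the membership with the highest modularity (ties broken by the
#' earliest restart), making the partition deterministic and robust to the
#' heuristic's occasional local optima on small graphs.
#'
#' @param g an igraph graph with named vertices.
#' @param restarts number of seeded restarts.
#' @param seed base RNG seed.
#' @return list with `membership` (named integer vector) and `modularity`.
#' @export
louvain_communities <- function(g, restarts = 20, seed = 1) {
  if (igraph::ecount(g) == 0) {
    # modularity is undefined without edges; use the singleton partition
    memb <- stats::setNames(seq_len(igraph::vcount(g)),
                            igraph::V(g)$name)
    return(list(membership = memb, modularity = 0))
  }
  best <- NULL
  best_q <- -Inf
  for (r in seq_len(restarts)) {
    comm <- withr::with_seed(as.integer(seed) + r - 1L,
                             igraph::cluster_louvain(g))
    memb <- igraph::membership(comm)
    q <- igraph::modularity(g, memb)
    if (q > best_q + 1e-12) {
      best_q <- q
      best <- memb
    }
  }
  list(membership = best, modularity = best_q)
}

#' Detect complex-QTL modules by community detection
#'
#' Builds one shared-signal graph per tissue from the QTL pairs and detects
#' communities by Louvain modularity maximization (igraph), run with
#' multiple seeded restarts via [louvain_communities()]. Vertices are
#' inserted in lexicographic order and the RNG seeds are fixed, so the
#' partition is deterministic. Communities of size >= 2 become complex-QTL
#' modules; QTLs with no edges (and communities of size 1) are singletons.
#'
#' @param pairs data.frame of shared pairs from [shared_qtl_pairs()].
#' @param records all primary QTL records (defines the QTL universe and the
#'   phenotype types used for the composition category).
#' @param seed RNG seed for the Louvain heuristic.
#' @return list with `modules` (data.frame module, tissue, element, type) and
#'   `singletons` (character vector of element ids), plus `categories`
#'   (data.frame module, tissue, category, size).
#' @export
detect_complex_modules <- function(pairs, records, seed = 1) {
  prim <- records[records$rank == "primary", , drop = FALSE]
  modules <- list()
  in_module <- character()
  mod_counter <- 0L
  for (tis in sort(unique(prim$tissue))) {
    pt <- pairs[pairs$tissue == tis, , drop = FALSE]
    if (nrow(pt) == 0) next
    verts <- sort(unique(c(pt$element1, pt$element2)))
    g <- igraph::graph_from_data_frame(
      pt[order(pt$element1, pt$element2), c("element1", "element2")],
      directed = FALSE, vertices = verts)
    memb <- louvain_communities(g, seed = seed)$membership
    for (cm in sort(unique(memb))) {
      members <- sort(names(memb)[memb == cm])
      if (length(members) < 2) next
      mod_counter <- mod_counter + 1L
      modules[[mod_counter]] <- data.frame(
        module = sprintf("mod%04d", mod_counter), tissue = tis,
        element = members,
        type = prim$type[match(members, prim$element)],
        stringsAsFactors = FALSE)
      in_module <- c(in_module, members)
    }
  }
  mod_df <- if (length(modules)) do.call(rbind, modules) else
    data.frame(module = character(), tissue = character(),
               element = character(), type = character())
  singletons <- setdiff(prim$element, in_module)
  cats <- if (nrow(mod_df)) {
    do.call(rbind, lapply(split(mod_df, mod_df$module), function(m) {
      data.frame(module = m$module[1], tissue = m$tissue[1],
                 category = composition_category(m$type),
                 size = nrow(m), stringsAsFactors = FALSE)
    }))
  } else {
    data.frame(module = character(), tissue = character(),
               category = character(), size = integer())
  }
  rownames(cats) <- NULL
  list(modules = mod_df, singletons = singletons, categories = cats)
}

# phenotype composition label of a module from its member element types
composition_category <- function(types) {
  has <- c(ca = any(types == "accessibility"),
           ha = any(types == "acetylation"),
           e = any(types == "expression"))
  parts <- c(if (has["ca"]) "caQTL", if (has["ha"]) "haQTL", if (has["e"]) "eQTL")
  paste(parts, collapse = "-")
}

#' Exhaustive modularity maximization (oracle for tiny graphs)
#'
#' Enumerates every partition of the vertex set (feasible up to ~10
#' vertices) and returns the partition with maximum Newman modularity; used
#' as the independent reference for community detection on toy graphs.
#'
#' @param g an igraph graph.
#' @return list with `membership` (named integer vector) and `modularity`.
#' @export
brute_force_modularity <- function(g) {
  n <- igraph::vcount(g)
  if (n > 10) stop("brute force limited to 10 vertices")
  if (igraph::ecount(g) == 0) {
    memb <- stats::setNames(seq_len(n), igraph::V(g)$name)
    return(list(membership = memb, modularity = 0))
  }
  # enumerate set partitions via restricted growth strings
  best <- NULL
  best_q <- -Inf
  rgs <- rep(1L, n)
  repeat {
    q <- igraph::modularity(g, rgs)
    if (q > best_q + 1e-12) {
      best_q <- q
      best <- rgs
    }
    # next restricted growth string
    i <- n
    while (i >= 2) {
      if (rgs[i] <= max(rgs[1:(i - 1)])) break
      i <- i - 1
    }
    if (i < 2) break
    rgs[i] <- rgs[i] + 1L
    if (i < n) rgs[(i + 1):n] <- 1L
  }
  names(best) <- igraph::V(g)$name
  list(membership = best, modularity = best_q)
}

#' Minimum distance from QTL lead variants to expressed-gene TSSs
#'
#' @param records QTL records with `pos` (lead variant position) and
#'   `chrom`.
#' @param gene_models data.frame of expressed genes with `chrom`, `strand`,
#'   `tss`.
#' @return numeric vector (bp), `NA` when the lead's chromosome carries no
#'   expressed gene.
#' @export
min_distance_to_tss <- function(records, gene_models) {
  vapply(seq_len(nrow(records)), function(i) {
    tss <- gene_models$tss[gene_models$chrom == records$chrom[i]]
    if (length(tss) == 0) return(NA_real_)
    min(abs(records$pos[i] - tss))
  }, numeric(1))
}
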