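#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei agglomeration with the Q-criterion; at each step the pair
#' minimizing Q is joined, ties broken deterministically by the smallest
#' pair of current node indices (label order). Negative branch-length
#' estimates are clamped to 0; the raw values are retained in attribute
#' `"clamped"`. On an additive distance matrix the generating topology and
#' branch lengths are recovered exactly.
#'
#' @param dm Symmetric labeled distance matrix (asymmetry beyond 1e-9 is an
#'   error). Two labels give the degenerate single-edge tree (represented
#'   with the edge split evenly between the tips).
#' @return An `ape::phylo` tree (unrooted for >= 3 taxa).
#' @export
neighbor_joining <- function(dm) {
  dm <- as.matrix(dm)
  labs <- rownames(dm)
  if (is.null(labs)) stop("distance matrix must have labels")
  if (max(abs(dm - t(dm))) > 1e-9) {
    stop("distance matrix is asymmetric beyond tolerance 1e-9")
  }
  n <- length(labs)
  if (n < 2) stop("need at least 2 taxa")
  clamped <- list()
  clamp <- function(x, a, b) {
    if (x < 0) {
      clamped[[length(clamped) + 1]] <<- tibble(node_a = a, node_b = b, raw = x)
      0
    } else x
  }
  fmt <- function(x) sprintf("%.15g", x)
  if (n == 2) {
    h <- dm[1, 2] / 2
    nwk <- sprintf("(%s:%s,%s:%s);", labs[1], fmt(h), labs[2], fmt(h))
    tr <- ape::read.tree(text = nwk)
    attr(tr, "clamped") <- dplyr::bind_rows(clamped)
    return(tr)
  }

  frag <- labs            # newick fragment per active node
  d <- dm
  active <- labs
  while (length(active) > 3) {
    m <- length(active)
    rs <- rowSums(d)
    # Q-criterion; scan in index order so ties pick the smallest (i, j)
    bi <- 1L; bj <- 2L; bq <- Inf
    for (i in seq_len(m - 1)) {
      for (j in (i + 1):m) {
        q <- (m - 2) * d[i, j] - rs[i] - rs[j]
        if (q < bq - 1e-12) { bq <- q; bi <- i; bj <- j }
      }
    }
    li <- d[bi, bj] / 2 + (rs[bi] - rs[bj]) / (2 * (m - 2))
    lj <- d[bi, bj] - li
    li <- clamp(li, active[bi], active[bj])
    lj <- clamp(lj, active[bj], active[bi])
    newfrag <- sprintf("(%s:%s,%s:%s)", frag[bi], fmt(li), frag[bj], fmt(lj))
    newd <- (d[bi, ] + d[bj, ] - d[bi, bj]) / 2
    keep <- setdiff(seq_len(m), c(bi, bj))
    d <- rbind(cbind(d[keep, keep, drop = FALSE], newd[keep]),
               c(newd[keep], 0))
    frag <- c(frag[keep], newfrag)
    active <- c(active[keep], paste0("(", active[bi], ",", active[bj], ")"))
  }
  # final three-point join
  l1 <- (d[1, 2] + d[1, 3] - d[2, 3]) / 2
  l2 <- (d[1, 2] + d[2, 3] - d[1, 3]) / 2
  l3 <- (d[1, 3] + d[2, 3] - d[1, 2]) / 2
  l1 <- clamp(l1, active[1], "center")
  l2 <- clamp(l2, active[2], "center")
  l3 <- clamp(l3, active[3], "center")
  nwk <- sprintf("(%s:%s,%s:%s,%s:%s);",
                 frag[1], fmt(l1), frag[2], fmt(l2), frag[3], fmt(l3))
  tr <- ape::read.tree(text = nwk)
  attr(tr, "clamped") <- dplyr::bind_rows(clamped)
  tr
}

# internal splits of a tree as canonical keys (sorted tip labels of the
# smaller side; ties broken by the side containing the alphabetically first
# label)
tree_splits <- function(tree) {
  n <- length(tree$tip.label)
  if (is.null(tree$node.label)) tree$node.label <- rep("", tree$Nnode)
  parts <- ape::prop.part(tree)
  keys <- character(0)
  nodes <- integer(0)
  for (k in seq_along(parts)) {
    side <- sort(tree$tip.label[parts[[k]]])
    if (length(side) < 2 || length(side) > n - 2) next
    comp <- sort(setdiff(tree$tip.label, side))
    key <- if (length(side) < length(comp) ||
               (length(side) == length(comp) && side[1] < comp[1])) side else comp
    keys <- c(keys, paste(key, collapse = "|"))
    nodes <- c(nodes, n + k)  # prop.part order follows internal node numbers
  }
  list(keys = keys, nodes = nodes)
}

#' Bootstrap support for a neighbor-joining tree
#'
#' Resamples MSA columns with replacement, rebuilds the p-distance NJ tree
#' per replicate, and reports for each internal split of the full-data tree
#' the percentage of replicate trees containing it. Fully seeded and
#' reproducible: identical seed and input give bit-identical supports.
#'
#' @param msa A [build_msa()] result.
#' @param replicates Number of bootstrap replicates (>= 1).
#' @param seed Integer seed for column resampling.
#' @return The full-data `phylo` tree with `node.label` carrying support
#'   values (0-100) on internal splits, plus attribute `"support"` (tibble
#'   of split keys and supports).
#' @export
bootstrap_support <- function(msa, replicates = 1000, seed = 1) {
  if (replicates < 1) stop("replicates must be >= 1")
  rows <- unclass(msa)
  L <- nchar(rows[[1]])
  chars <- do.call(rbind, strsplit(unname(rows), "", fixed = TRUE))
  rownames(chars) <- names(rows)
  full <- neighbor_joining(pdistance_matrix(msa))
  sp <- tree_splits(full)
  counts <- setNames(rep(0L, length(sp$keys)), sp$keys)
  withr::with_seed(seed, {
    for (r in seq_len(replicates)) {
      cols <- sample.int(L, L, replace = TRUE)
      rep_rows <- apply(chars[, cols, drop = FALSE], 1, paste, collapse = "")
      rep_tree <- neighbor_joining(pdistance_matrix(rep_rows))
      rep_keys <- tree_splits(rep_tree)$keys
      hit <- sp$keys %in% rep_keys
      counts[hit] <- counts[hit] + 1L
    }
  })
  support <- 100 * counts / replicates
  if (is.null(full$node.label)) full$node.label <- rep("", full$Nnode)
  n <- length(full$tip.label)
  for (k in seq_along(sp$nodes)) {
    full$node.label[sp$nodes[k] - n] <- format(support[k])
  }
  attr(full, "support") <- tibble(split = sp$keys, support = unname(support))
  attr(full, "replicates") <- replicates
  attr(full, "seed") <- seed
  full
}

#' Write / read trees in Newick format
#'
#' Thin wrappers around `ape::write.tree()` / `ape::read.tree()`; bootstrap
#' supports travel as internal-node labels.
#'
#' @param tree An `ape::phylo`.
#' @param path File path.
#' @return `write_newick`: invisibly `path`; `read_newick`: a `phylo`.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path, digits = 15)
  invisible(path)
}

#' @rdname write_newick
#' @export
read_newick <- function(path) {
  ape::read.tree(path)
}

#' Write a distance matrix in PHYLIP square format
#'
#' @param dm Labeled symmetric matrix.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_phylip <- function(dm, path) {
  labs <- rownames(dm)
  lines <- c(sprintf("%5d", nrow(dm)),
             vapply(seq_len(nrow(dm)), function(i) {
               paste0(formatC(labs[i], width = -10),
                      paste(sprintf("%.6f", dm[i, ]), collapse = " "))
             }, character(1)))
  writeLines(lines, path)
  invisible(path)
}
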