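#' Progressive multiple sequence alignment
#'
#' Builds an MSA by progressive alignment: pairwise global alignments give
#' identity distances, a UPGMA guide tree orders the merges, and profiles
#' are merged by profile-profile affine-gap alignment. A star alignment
#' around the centroid sequence (highest total pairwise score) is built as a
#' second candidate, and whichever of the two scores higher under the
#' affine sum-of-pairs criterion is returned (ties favour the progressive
#' result). This guarantees the returned MSA never scores below the naive
#' star alignment.
#'
#' @param seqs Named character vector of >= 2 amino-acid sequences.
#' @param scheme A [scoring_scheme()].
#' @return Object of class `pga_msa`: named character vector of equal-length
#'   gapped rows, in input order.
#' @export
build_msa <- function(seqs, scheme = scoring_scheme()) {
  seqs <- unlist(seqs)
  n <- length(seqs)
  if (n < 2) stop("build_msa needs at least 2 sequences")
  if (is.null(names(seqs))) names(seqs) <- paste0("seq", seq_len(n))
  for (s in seqs) check_sequence(s, scheme$alphabet)

  # pairwise scores and identity distances
  score <- matrix(0, n, n)
  dist <- matrix(0, n, n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      al <- align_pair(seqs[[i]], seqs[[j]], scheme)
      score[i, j] <- score[j, i] <- al$score
      dist[i, j] <- dist[j, i] <- 1 - al$identity
    }
  }

  prog <- progressive_msa(seqs, dist, scheme)
  star <- star_msa(seqs, score, scheme)
  sp_p <- sp_score_cpp(unname(prog), scheme$matrix, scheme$alphabet,
                       scheme$gap_open, scheme$gap_extend)
  sp_s <- sp_score_cpp(unname(star), scheme$matrix, scheme$alphabet,
                       scheme$gap_open, scheme$gap_extend)
  rows <- if (sp_s > sp_p) star else prog
  structure(rows[names(seqs)], class = "pga_msa")
}

progressive_msa <- function(seqs, dist, scheme) {
  n <- length(seqs)
  # UPGMA agglomeration over the identity distances; deterministic
  # tie-break: smallest (i, j) pair in current cluster order.
  clusters <- lapply(seq_len(n), function(i) {
    list(members = i, profile = setNames(seqs[i], names(seqs)[i]), size = 1)
  })
  d <- dist
  while (length(clusters) > 1) {
    best <- c(1L, 2L)
    bv <- Inf
    for (i in seq_len(length(clusters) - 1)) {
      for (j in (i + 1):length(clusters)) {
        if (d[i, j] < bv - 1e-15) { bv <- d[i, j]; best <- c(i, j) }
      }
    }
    i <- best[1]; j <- best[2]
    merged_profile <- merge_profiles(clusters[[i]]$profile,
                                     clusters[[j]]$profile, scheme)
    ni <- clusters[[i]]$size; nj <- clusters[[j]]$size
    newd <- (d[i, ] * ni + d[j, ] * nj) / (ni + nj)
    keep <- setdiff(seq_along(clusters), c(i, j))
    d <- d[keep, keep, drop = FALSE]
    if (length(keep) > 0) {
      d <- rbind(cbind(d, newd[keep]), c(newd[keep], 0))
    } else {
      d <- matrix(0, 1, 1)
    }
    clusters <- c(clusters[keep],
                  list(list(members = c(clusters[[i]]$members,
                                        clusters[[j]]$members),
                            profile = merged_profile, size = ni + nj)))
  }
  clusters[[1]]$profile
}

merge_profiles <- function(pa, pb, scheme) {
  res <- profile_align_cpp(unname(pa), unname(pb), scheme$matrix,
                           scheme$alphabet, scheme$gap_open, scheme$gap_extend)
  setNames(res$rows, c(names(pa), names(pb)))
}

star_msa <- function(seqs, score, scheme) {
  n <- length(seqs)
  tot <- rowSums(score)
  center <- which.max(tot)  # first maximum: deterministic
  others <- setdiff(seq_len(n), center)
  master <- seqs[[center]]          # gapped center in the master alignment
  rows <- list()                    # gapped others, synchronized to master
  for (k in others) {
    al <- align_pair(seqs[[center]], seqs[[k]], scheme)
    sync <- sync_to_master(master, al$aligned_a, al$aligned_b, rows)
    master <- sync$master
    rows <- sync$rows
    rows[[as.character(k)]] <- sync$new_row
  }
  out <- setNames(character(n), names(seqs))
  out[center] <- master
  for (k in others) out[k] <- rows[[as.character(k)]]
  out
}

# Merge a new pairwise alignment (c_aln vs s_aln, where c_aln de-gaps to the
# center) into the master alignment, padding previous rows ("once a gap,
# always a gap").
sync_to_master <- function(master, c_aln, s_aln, rows) {
  m <- strsplit(master, "", fixed = TRUE)[[1]]
  ca <- strsplit(c_aln, "", fixed = TRUE)[[1]]
  sa <- strsplit(s_aln, "", fixed = TRUE)[[1]]
  out_m <- character(0); out_s <- character(0)
  ins_master <- integer(0)  # output columns where master gained a gap
  ins_caln <- integer(0)    # output columns where c_aln gained a gap
  i <- 1L; j <- 1L
  while (i <= length(m) || j <= length(ca)) {
    mi <- if (i <= length(m)) m[i] else NULL
    cj <- if (j <= length(ca)) ca[j] else NULL
    if (!is.null(mi) && mi == "-" && (is.null(cj) || cj != "-")) {
      out_m <- c(out_m, "-"); out_s <- c(out_s, "-")
      ins_caln <- c(ins_caln, length(out_m))
      i <- i + 1L
    } else if (!is.null(cj) && cj == "-" && (is.null(mi) || mi != "-")) {
      out_m <- c(out_m, "-"); out_s <- c(out_s, sa[j])
      ins_master <- c(ins_master, length(out_m))
      j <- j + 1L
    } else {
      out_m <- c(out_m, mi); out_s <- c(out_s, sa[j])
      i <- i + 1L; j <- j + 1L
    }
  }
  # pad previously merged rows at the columns where master gained gaps
  if (length(ins_master) > 0 && length(rows) > 0) {
    rows <- lapply(rows, function(r) {
      rc <- strsplit(r, "", fixed = TRUE)[[1]]
      res <- character(length(out_m))
      src <- 1L
      for (col in seq_along(out_m)) {
        if (col %in% ins_master) res[col] <- "-"
        else { res[col] <- rc[src]; src <- src + 1L }
      }
      paste(res, collapse = "")
    })
  }
  list(master = paste(out_m, collapse = ""),
       new_row = paste(out_s, collapse = ""), rows = rows)
}

#' @export
print.pga_msa <- function(x, ...) {
  cat(sprintf("<pga_msa> %d sequences x %d columns\n",
              length(x), nchar(x[[1]])))
  invisible(x)
}

#' Write an MSA as aligned multi-FASTA
#'
#' @param msa A `pga_msa`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_msa_fasta <- function(msa, path) {
  lines <- as.vector(rbind(paste0(">", names(msa)), unname(unclass(msa))))
  writeLines(lines, path)
  invisible(path)
}

#' p-distance matrix from an MSA (pairwise deletion)
#'
#' `d(i, j)` is the fraction of mismatched columns among columns where
#' neither row has a gap. Pairwise deletion keeps a divergent, gap-rich
#' sequence from discarding columns for every other pair.
#'
#' @param msa A `pga_msa` (or named character vector of equal-length gapped
#'   rows).
#' @return Symmetric labeled matrix of p-distances in `[0, 1]`.
#' @export
pdistance_matrix <- function(msa) {
  rows <- unclass(msa)
  n <- length(rows)
  labs <- names(rows)
  chars <- lapply(rows, function(r) strsplit(r, "", fixed = TRUE)[[1]])
  m <- matrix(0, n, n, dimnames = list(labs, labs))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      both <- chars[[i]] != "-" & chars[[j]] != "-"
      if (!any(both)) {
        stop(sprintf("no comparable columns between %s and %s",
                     labs[i], labs[j]))
      }
      p <- sum(chars[[i]][both] != chars[[j]][both]) / sum(both)
      m[i, j] <- m[j, i] <- p
    }
  }
  m
}

#' Number of distinct sequence variants (haplotypes)
#'
#' The package's branch-diversity proxy: distinct protein strings in a panel.
#'
#' @param seqs Character vector of sequences.
#' @return Integer count of unique sequences.
#' @export
count_variants <- function(seqs) {
  if (length(seqs) < 1) stop("count_variants needs at least one sequence")
  length(unique(unlist(seqs)))
}
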