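# JC69 divergence of precursor sequences and the per-subgenome rate
# comparison.

#' Jukes-Cantor (JC69) distance between two aligned sequences
#'
#' `d = -(3/4) * ln(1 - (4/3) * p)` where `p` is the mismatch proportion
#' over columns where neither sequence has a gap. Saturation (`p >= 3/4`)
#' has no finite JC69 distance and is an error.
#'
#' @param seq_a,seq_b aligned nucleotide strings of equal length; `-`
#'   columns are excluded pairwise.
#' @return substitutions per site (>= 0).
#' @export
jc69_distance <- function(seq_a, seq_b) {
  if (nchar(seq_a) != nchar(seq_b)) {
    stop("sequences must be aligned to equal length")
  }
  a <- strsplit(toupper(seq_a), "", fixed = TRUE)[[1L]]
  b <- strsplit(toupper(seq_b), "", fixed = TRUE)[[1L]]
  keep <- a != "-" & b != "-"
  if (!any(keep)) stop("no comparable (gap-free) columns")
  p <- mean(a[keep] != b[keep])
  jc69_from_p(p)
}

jc69_from_p <- function(p) {
  if (any(p >= 0.75)) {
    stop("mismatch proportion >= 3/4: JC69 distance is saturated")
  }
  -0.75 * log(1 - 4 * p / 3)
}

# integer-coded alignment matrix (rows = sequences); gaps/ambiguity -> NA
seq_matrix <- function(seqs) {
  n <- length(seqs)
  L <- nchar(seqs[1L])
  if (any(nchar(seqs) != L)) stop("sequences must have equal length")
  matrix(match(unlist(strsplit(toupper(seqs), "", fixed = TRUE)), BASES),
         nrow = n, ncol = L, byrow = TRUE)
}

#' Column-plurality consensus of aligned sequences
#'
#' Majority base per column; ties break deterministically to the
#' alphabetically first base. Gap/ambiguous characters do not vote.
#'
#' @param seqs character vector of equal-length aligned sequences.
#' @return the consensus string.
#' @export
consensus_sequence <- function(seqs) {
  m <- seq_matrix(seqs)
  counts <- vapply(seq_along(BASES),
                   function(b) colSums(m == b, na.rm = TRUE),
                   numeric(ncol(m)))
  if (ncol(m) == 1L) counts <- matrix(counts, nrow = 1L)
  paste(BASES[max.col(counts, ties.method = "first")], collapse = "")
}

#' Per-subgenome substitution-rate summary with ANOVA
#'
#' For every taxon, families represented on at least one alpha and one
#' beta subgenome contribute their precursor paralogs; each paralog's JC69
#' divergence from the family's column-plurality consensus (built over the
#' family's sequences within that taxon) is averaged per taxon x
#' subgenome. A one-way ANOVA then contrasts the per-taxon mean divergences
#' of two subgenome groups (default 2a vs 2b, the slots with the most and
#' the fewest retained paralogs), with the p-value from the F survival
#' function.
#'
#' Families with fewer than two sequences in a taxon are excluded (no
#' consensus contrast); saturated paralogs are excluded with a log entry in
#' attribute `excluded`.
#'
#' @param seq_table `data.frame(taxon, family, subgenome, pre_seq)` of
#'   aligned (here: fixed-length) precursors.
#' @param groups the two subgenome slots contrasted by the ANOVA.
#' @param paired_only require >= 1 alpha and >= 1 beta paralog per family
#'   and taxon?
#' @return a list of class `rate_summary`: `per_group`
#'   (taxon x subgenome mean divergence and n), `anova` (a `mirna_test`
#'   with the F statistic and df pair), and `group_means`.
#' @export
subgenome_rate_summary <- function(seq_table, groups = c("2a", "2b"),
                                   paired_only = TRUE) {
  need <- c("taxon", "family", "subgenome", "pre_seq")
  stopifnot(all(need %in% names(seq_table)))
  if (length(groups) != 2L) stop("groups must name exactly two subgenomes")

  acc_tx <- list(); acc_fam <- list(); acc_sub <- list(); acc_div <- list()
  exc_tx <- list(); exc_fam <- list(); exc_why <- list()
  for (tx in unique(seq_table$taxon)) {
    st <- seq_table[seq_table$taxon == tx, , drop = FALSE]
    if (paired_only) {
      cls <- subgenome_class(st$subgenome)
      has_a <- tapply(cls == "alpha", st$family, any)
      has_b <- tapply(cls == "beta", st$family, any)
      keep_f <- names(has_a)[which(has_a & has_b)]
      st <- st[st$family %in% keep_f, , drop = FALSE]
    }
    idx_by_fam <- split(seq_len(nrow(st)), st$family)
    for (fam in names(idx_by_fam)) {
      rows <- st[idx_by_fam[[fam]], , drop = FALSE]
      if (nrow(rows) < 2L) {
        exc_tx[[length(exc_tx) + 1L]] <- tx
        exc_fam[[length(exc_fam) + 1L]] <- fam
        exc_why[[length(exc_why) + 1L]] <- "single sequence"
        next
      }
      m <- seq_matrix(rows$pre_seq)
      cvec <- seq_matrix(consensus_sequence(rows$pre_seq))[1L, ]
      cmp <- m != matrix(cvec, nrow(m), ncol(m), byrow = TRUE)
      p <- rowMeans(cmp, na.rm = TRUE)
      sat <- p >= 0.75
      if (any(sat)) {
        exc_tx[[length(exc_tx) + 1L]] <- rep(tx, sum(sat))
        exc_fam[[length(exc_fam) + 1L]] <- rep(fam, sum(sat))
        exc_why[[length(exc_why) + 1L]] <- rep("saturated", sum(sat))
      }
      if (any(!sat)) {
        acc_tx[[length(acc_tx) + 1L]] <- rep(tx, sum(!sat))
        acc_fam[[length(acc_fam) + 1L]] <- rep(fam, sum(!sat))
        acc_sub[[length(acc_sub) + 1L]] <- rows$subgenome[!sat]
        acc_div[[length(acc_div) + 1L]] <- jc69_from_p(p[!sat])
      }
    }
  }
  if (!length(acc_div)) stop("no usable family alignments")
  div <- data.frame(taxon = unlist(acc_tx), family = unlist(acc_fam),
                    subgenome = unlist(acc_sub),
                    divergence = unlist(acc_div), stringsAsFactors = FALSE)
  excluded <- data.frame(taxon = unlist(exc_tx) %||% character(0),
                         family = unlist(exc_fam) %||% character(0),
                         reason = unlist(exc_why) %||% character(0),
                         stringsAsFactors = FALSE)

  agg <- stats::aggregate(divergence ~ taxon + subgenome, data = div,
                          FUN = mean)
  nloc <- stats::aggregate(divergence ~ taxon + subgenome, data = div,
                           FUN = length)
  per_group <- data.frame(taxon = agg$taxon, subgenome = agg$subgenome,
                          mean_divergence = agg$divergence,
                          n_loci = nloc$divergence,
                          stringsAsFactors = FALSE)

  x1 <- per_group$mean_divergence[per_group$subgenome == groups[1L]]
  x2 <- per_group$mean_divergence[per_group$subgenome == groups[2L]]
  if (length(x1) < 2L || length(x2) < 2L) {
    stop("ANOVA needs per-taxon means in both groups (>= 2 taxa each)")
  }
  n1 <- length(x1)
  n2 <- length(x2)
  grand <- mean(c(x1, x2))
  ss_between <- n1 * (mean(x1) - grand)^2 + n2 * (mean(x2) - grand)^2
  ss_within <- sum((x1 - mean(x1))^2) + sum((x2 - mean(x2))^2)
  d1 <- 1L
  d2 <- n1 + n2 - 2L
  fstat <- if (ss_within == 0) {
    if (ss_between == 0) 0 else Inf  # degenerate: identical values
  } else {
    (ss_between / d1) / (ss_within / d2)
  }
  anova <- new_mirna_test(fstat, c(d1, d2), f_sf(fstat, d1, d2),
                          sprintf("one-way ANOVA (%s vs %s mean divergence)",
                                  groups[1L], groups[2L]))
  structure(
    list(per_group = per_group, anova = anova,
         group_means = stats::setNames(c(mean(x1), mean(x2)), groups),
         divergences = div, excluded = excluded),
    class = "rate_summary"
  )
}

#' @export
print.rate_summary <- function(x, ...) {
  cat("Per-subgenome JC69 divergence (mean over taxa):\n")
  means <- tapply(x$per_group$mean_divergence, x$per_group$subgenome, mean)
  print(round(means, 5))
  print(x$anova)
  invisible(x)
}
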