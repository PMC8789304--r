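# Mature-miRNA expression comparisons across subgenomes.

#' Keep only loci with unique mature sequences
#'
#' Paralogs sharing a mature sequence cannot be told apart in small-RNA
#' read data, so their read counts would be spuriously merged. This filter
#' removes every locus whose 5p or 3p mature sequence occurs more than once
#' among all mature sequences of the taxon (all sharers are removed, not
#' just duplicates).
#'
#' @param loci locus table of one taxon with mature sequences.
#' @return the retained subset, with attribute `removed`
#'   (`data.frame(locus_id, reason)`).
#' @export
filter_unique_mature <- function(loci) {
  validate_loci(loci, require_seqs = TRUE)
  seqs <- c(loci$mature5p, loci$mature3p)
  counts <- table(seqs)
  dup5 <- counts[loci$mature5p] > 1L
  dup3 <- counts[loci$mature3p] > 1L
  drop <- as.vector(dup5 | dup3)
  out <- loci[!drop, , drop = FALSE]
  rownames(out) <- NULL
  reason <- ifelse(dup5[drop] & dup3[drop], "both arms shared",
                   ifelse(dup5[drop], "5p arm shared", "3p arm shared"))
  attr(out, "removed") <- data.frame(locus_id = loci$locus_id[drop],
                                     reason = as.vector(reason),
                                     stringsAsFactors = FALSE)
  out
}

#' Expression summary per subgenome
#'
#' Joins an rpm table to the loci and summarizes expression per subgenome
#' slot and per pooled side. By default only families represented on at
#' least one alpha and one beta subgenome are kept (the pairing criterion:
#' expression is compared between homeologs, not between unrelated
#' families). Apply [filter_unique_mature()] beforehand when working from
#' merged small-RNA reads.
#'
#' @param expr `data.frame(locus_id, rpm)`.
#' @param loci locus table.
#' @param paired_only keep only alpha/beta-paired families?
#' @return a list of class `expression_summary`: `per_subgenome` (n,
#'   median rpm, total reads per slot), `pooled` (same for alpha, beta, 1,
#'   2), and `ratios` (`beta_vs_alpha`, `one_vs_two` of pooled medians;
#'   `NA` when a side is empty).
#' @export
expression_by_subgenome <- function(expr, loci, paired_only = TRUE) {
  validate_loci(loci)
  stopifnot(all(c("locus_id", "rpm") %in% names(expr)))
  loci$rpm <- expr$rpm[match(loci$locus_id, expr$locus_id)]
  loci <- loci[!is.na(loci$rpm), , drop = FALSE]

  if (paired_only) {
    cls <- subgenome_class(loci$subgenome)
    has_a <- tapply(cls == "alpha", loci$family, any)
    has_b <- tapply(cls == "beta", loci$family, any)
    paired <- names(has_a)[which(has_a & has_b)]
    loci <- loci[loci$family %in% paired, , drop = FALSE]
  }

  summarize <- function(rows) {
    data.frame(n = nrow(rows),
               median_rpm = if (nrow(rows)) stats::median(rows$rpm) else NA_real_,
               total_reads = sum(rows$rpm))
  }
  per_sub <- do.call(rbind, lapply(SUBGENOME_SLOTS, function(s) {
    cbind(data.frame(subgenome = s, stringsAsFactors = FALSE),
          summarize(loci[loci$subgenome == s, , drop = FALSE]))
  }))

  cls <- subgenome_class(loci$subgenome)
  side <- subgenome_side(loci$subgenome)
  pooled <- do.call(rbind, list(
    cbind(data.frame(group = "alpha"), summarize(loci[cls %in% "alpha", ])),
    cbind(data.frame(group = "beta"), summarize(loci[cls %in% "beta", ])),
    cbind(data.frame(group = "1"), summarize(loci[side %in% "1", ])),
    cbind(data.frame(group = "2"), summarize(loci[side %in% "2", ]))
  ))

  med <- stats::setNames(pooled$median_rpm, pooled$group)
  ratio <- function(a, b) {
    if (is.na(med[a]) || is.na(med[b]) || med[b] == 0) NA_real_
    else unname(med[a] / med[b])
  }
  structure(
    list(per_subgenome = per_sub, pooled = pooled,
         ratios = c(beta_vs_alpha = ratio("beta", "alpha"),
                    one_vs_two = ratio("1", "2"))),
    class = "expression_summary"
  )
}

#' @export
print.expression_summary <- function(x, ...) {
  cat("Expression by subgenome:\n")
  print(x$per_subgenome, row.names = FALSE)
  cat(sprintf("median ratios: beta/alpha = %.3f, 1/2 = %.3f\n",
              x$ratios["beta_vs_alpha"], x$ratios["one_vs_two"]))
  invisible(x)
}

#' Test for subgenome-biased expression
#'
#' Chi-square goodness-of-fit (df = 1) of the pooled total reads on the
#' alpha vs beta side against an expectation proportional to the number of
#' loci on each side: under no expression bias, reads should scale with
#' locus counts.
#'
#' @param summary an [expression_by_subgenome()] result.
#' @return a `mirna_test`.
#' @export
expression_bias_test <- function(summary) {
  stopifnot(inherits(summary, "expression_summary"))
  p <- summary$pooled
  obs <- stats::setNames(p$total_reads[match(c("alpha", "beta"), p$group)],
                         c("alpha", "beta"))
  n <- stats::setNames(p$n[match(c("alpha", "beta"), p$group)],
                       c("alpha", "beta"))
  if (any(n == 0)) stop("both pooled subgenomes need at least one locus")
  res <- chisq_gof(obs, n)
  res$test_name <- "expression bias (alpha vs beta, reads vs locus counts)"
  res
}
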