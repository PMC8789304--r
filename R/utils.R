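# Internal helpers shared across modules.

# Canonical subgenome slots after two rounds of WGD (auto then allo).
# ASCII on disk and in memory; pretty_subgenome() maps to the Greek forms
# 1α, 2α, 1β, 2β for display.
SUBGENOME_SLOTS <- c("1a", "2a", "1b", "2b")

BASES <- c("A", "C", "G", "T")

`%||%` <- function(a, b) if (is.null(a)) b else a

is_count <- function(x, min = 0L) {
  length(x) == 1L && is.numeric(x) && !is.na(x) && x >= min && x == round(x)
}

is_prob <- function(x) {
  is.numeric(x) && !anyNA(x) && all(x >= 0) && all(x <= 1)
}

#' Display form of a subgenome label
#'
#' Maps the ASCII labels used on disk (`1a`, `2a`, `1b`, `2b`) to the
#' conventional Greek forms (1α, 2α, 1β, 2β).
#'
#' @param label character vector of subgenome labels.
#' @return character vector with `a`/`b` suffixes replaced by alpha/beta.
#' @export
pretty_subgenome <- function(label) {
  out <- sub("a$", "α", label)
  sub("b$", "β", out)
}

# alpha/beta class of a label: labels ending in "a" are alpha-derived, in "b"
# beta-derived; pre-allotetraploidy labels ("1", "2", "none") have no class.
subgenome_class <- function(label) {
  cls <- rep(NA_character_, length(label))
  cls[grepl("a$", label)] <- "alpha"
  cls[grepl("b$", label)] <- "beta"
  cls
}

# first-WGD side ("1" or "2") of a label; NA for "none".
subgenome_side <- function(label) {
  side <- substr(label, 1L, 1L)
  side[!side %in% c("1", "2")] <- NA_character_
  side
}

# Conventional paralog labels: P1 = 1a, P2 = 2a, P3 = 1b, P4 = 2b,
# and after a single WGD P1 = 1, P2 = 2. Other labels map to "".
paralog_label_for <- function(subgenome) {
  map <- c("1a" = "P1", "2a" = "P2", "1b" = "P3", "2b" = "P4",
           "1" = "P1", "2" = "P2")
  out <- unname(map[subgenome])
  out[is.na(out)] <- ""
  out
}

# Named-vector lookup with a default for absent keys.
lookup <- function(map, keys, default) {
  if (is.null(map) || length(map) == 0L) {
    return(rep(default, length(keys)))
  }
  out <- unname(map[keys])
  out[is.na(out)] <- default
  out
}

new_mirna_test <- function(statistic, df, p_value, test_name,
                           observed = NULL, expected = NULL) {
  structure(
    list(statistic = statistic, df = df, p_value = p_value,
         test_name = test_name, observed = observed, expected = expected),
    class = "mirna_test"
  )
}

#' @export
print.mirna_test <- function(x, ...) {
  df <- paste(x$df, collapse = ", ")
  cat(sprintf("%s: statistic = %.4g, df = %s, p = %.4g\n",
              x$test_name, x$statistic, df, x$p_value))
  if (!is.null(x$observed)) {
    cat("  observed:", paste(signif(x$observed, 6), collapse = " "), "\n")
  }
  if (!is.null(x$expected)) {
    cat("  expected:", paste(signif(x$expected, 6), collapse = " "), "\n")
  }
  invisible(x)
}

# Columns every locus table must carry (sequences and rpm are optional).
LOCUS_COLUMNS <- c("locus_id", "family", "paralog_label", "contig", "start",
                   "end", "strand", "subgenome", "node_of_origin")

validate_loci <- function(loci, require_seqs = FALSE) {
  stopifnot(is.data.frame(loci))
  missing <- setdiff(LOCUS_COLUMNS, names(loci))
  if (length(missing)) {
    stop("locus table is missing columns: ", paste(missing, collapse = ", "))
  }
  if (nrow(loci)) {
    if (any(loci$start < 0) || any(loci$end <= loci$start)) {
      bad <- which(loci$start < 0 | loci$end <= loci$start)[1L]
      stop(sprintf("invalid coordinates for locus '%s': start=%d end=%d ",
                   loci$locus_id[bad], loci$start[bad], loci$end[bad]),
           "(0-based half-open; start must be >= 0 and < end)")
    }
  }
  if (require_seqs && !all(c("pre_seq", "mature5p", "mature3p") %in% names(loci))) {
    stop("locus table lacks sequence columns (pre_seq, mature5p, mature3p)")
  }
  invisible(loci)
}
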