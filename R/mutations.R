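## Mutation burden profiling and pathway-level collapse.

NONSILENT_CLASSES <- c(
  "missense", "truncating", "nonsense", "frameshift", "splice_site",
  "Missense_Mutation", "Nonsense_Mutation", "Frame_Shift_Del",
  "Frame_Shift_Ins", "In_Frame_Del", "In_Frame_Ins", "Splice_Site",
  "Nonstop_Mutation", "Translation_Start_Site")
SILENT_CLASSES <- c("silent", "synonymous", "Silent", "3'UTR", "5'UTR",
                    "3'Flank", "5'Flank", "Intron", "IGR", "RNA")

#' Read a MAF-like mutation table
#'
#' Accepts either the package's simple schema (`sample`, `gene`, `class`) or
#' MAF column names (`Tumor_Sample_Barcode`, `Hugo_Symbol`,
#' `Variant_Classification`).
#'
#' @param path tab-delimited file path.
#' @return data frame with columns `sample`, `gene`, `class`.
#' @export
read_mutations <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  maf_map <- c(Tumor_Sample_Barcode = "sample", Hugo_Symbol = "gene",
               Variant_Classification = "class")
  hit <- intersect(names(maf_map), colnames(df))
  colnames(df)[match(hit, colnames(df))] <- maf_map[hit]
  need <- c("sample", "gene", "class")
  if (!all(need %in% colnames(df))) {
    stop("mutation table needs columns sample/gene/class (or MAF names)",
         call. = FALSE)
  }
  df[need]
}

#' Per-sample mutation burden profile
#'
#' Counts non-silent variants per sample (silent/synonymous classes are
#' excluded), converts them to a per-megabase rate over the sequencing
#' capture, and flags hypermutated samples at `rate_threshold` or more
#' variants. Also returns the per-gene binary mutation matrix.
#'
#' @param mutations data frame with columns `sample`, `gene`, `class` (see
#'   [read_mutations()]).
#' @param samples character vector of all sample ids (so samples without
#'   variants count as zero).
#' @param capture_mb size of the sequenced target in megabases (default
#'   3.2).
#' @param rate_threshold variant count from which a sample is flagged as
#'   hypermutated (default 10).
#' @param strict if `TRUE`, unknown variant classes are an error; otherwise
#'   they are counted as non-silent with a warning.
#' @return object of class `mutation_profile`: list with `counts` (per
#'   sample), `rate_per_mb`, `high_rate` (logical), `gene_matrix` (gene x
#'   sample 0/1, non-silent only), `capture_mb`, `rate_threshold`.
#' @export
mutation_profile <- function(mutations, samples, capture_mb = 3.2,
                             rate_threshold = 10, strict = FALSE) {
  if (capture_mb <= 0) stop("capture_mb must be positive", call. = FALSE)
  cls <- mutations$class
  known <- cls %in% c(NONSILENT_CLASSES, SILENT_CLASSES)
  if (any(!known)) {
    msg <- paste("unknown variant class(es):",
                 paste(unique(cls[!known]), collapse = ", "))
    if (strict) stop(msg, call. = FALSE)
    warning(msg, "; counted as non-silent")
  }
  nonsilent <- mutations[!(cls %in% SILENT_CLASSES), , drop = FALSE]
  counts <- table(factor(nonsilent$sample, levels = samples))
  counts <- stats::setNames(as.integer(counts), samples)
  gene_matrix <- if (nrow(nonsilent)) {
    tab <- table(factor(nonsilent$gene), factor(nonsilent$sample,
                                                levels = samples))
    m <- matrix(as.integer(tab > 0), nrow(tab), ncol(tab),
                dimnames = dimnames(tab))
    m
  } else {
    matrix(0L, 0, length(samples), dimnames = list(NULL, samples))
  }
  structure(list(counts = counts, rate_per_mb = counts / capture_mb,
                 high_rate = counts >= rate_threshold,
                 gene_matrix = gene_matrix, capture_mb = capture_mb,
                 rate_threshold = rate_threshold),
            class = "mutation_profile")
}

#' @export
print.mutation_profile <- function(x, ...) {
  cat("mutation_profile:", length(x$counts), "samples;",
      "median non-silent count", stats::median(x$counts), ";",
      sum(x$high_rate), "hypermutated (>=", x$rate_threshold, ")\n")
  invisible(x)
}

#' Collapse mutations to pathway level
#'
#' Marks a sample as pathway-mutated when any member gene carries a
#' non-silent variant, and summarizes mutual exclusivity: the observed
#' number of samples with two or more member genes mutated against its
#' expectation (and binomial standard deviation) under per-gene
#' independence.
#'
#' @param gene_matrix gene x sample 0/1 matrix (e.g. from
#'   [mutation_profile()]).
#' @param gene_set character vector of pathway member genes.
#' @return list with `pathway_mutated` (named 0/1 per sample), `frequency`
#'   (fraction of samples pathway-mutated), `observed_comutated`,
#'   `expected_comutated` and `sd_comutated`.
#' @export
pathway_collapse <- function(gene_matrix, gene_set) {
  if (length(gene_set) == 0) stop("gene_set must be non-empty", call. = FALSE)
  members <- intersect(gene_set, rownames(gene_matrix))
  n <- ncol(gene_matrix)
  if (length(members) == 0) {
    return(list(pathway_mutated = stats::setNames(rep(0L, n),
                                                  colnames(gene_matrix)),
                frequency = 0, observed_comutated = 0L,
                expected_comutated = 0, sd_comutated = 0))
  }
  sub <- gene_matrix[members, , drop = FALSE]
  n_mut <- colSums(sub)
  marg <- rowMeans(sub)
  ## P(>= 2 members mutated) under independence
  p_none <- prod(1 - marg)
  p_one <- sum(vapply(seq_along(marg), function(i) {
    marg[i] * prod(1 - marg[-i])
  }, numeric(1)))
  p_two_plus <- max(0, 1 - p_none - p_one)
  list(pathway_mutated = stats::setNames(as.integer(n_mut > 0),
                                         colnames(gene_matrix)),
       frequency = mean(n_mut > 0),
       observed_comutated = sum(n_mut >= 2),
       expected_comutated = n * p_two_plus,
       sd_comutated = sqrt(n * p_two_plus * (1 - p_two_plus)))
}
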