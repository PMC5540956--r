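#' Confusion (overlap) table between two partitions
#'
#' Counts `N_ij`, the number of nodes shared by community `i` of partition
#' `a` and community `j` of partition `b`, the basis of NMI and of the
#' biggest-overlap matching.
#'
#' @param a,b partitions of the same node set (label vectors of equal
#'   length).
#' @return A list of class `confusion_table` with integer matrix `counts`,
#'   `row_sums`, `col_sums` and `total`.
#' @export
confusion_table <- function(a, b) {
  a <- as.vector(a); b <- as.vector(b)
  if (length(a) != length(b) || length(a) == 0 || anyNA(a) || anyNA(b))
    stop("partitions must cover the same non-empty node set")
  counts <- unclass(table(as.integer(as.factor(a)),
                          as.integer(as.factor(b))))
  dimnames(counts) <- NULL
  structure(list(counts = counts, row_sums = rowSums(counts),
                 col_sums = colSums(counts), total = length(a)),
            class = "confusion_table")
}

#' Normalized Mutual Information between two partitions
#'
#' NMI(A, B) = -2 sum_ij N_ij ln(N_ij N / (N_i. N_.j)) /
#' \[sum_i N_i. ln(N_i./N) + sum_j N_.j ln(N_.j/N)\], evaluated on the
#' overlap table; terms with N_ij = 0 contribute 0. The value is 0 when the
#' retrieved structure carries no information about the reference (e.g.
#' against the single-community partition) and 1 for identical partitions;
#' when both partitions are the trivial single community the 0/0 form is
#' resolved to 1 (identical partitions). The logarithm base cancels.
#'
#' @inheritParams confusion_table
#' @return NMI in \[0, 1\].
#' @examples
#' nmi(c(1, 1, 1, 2, 2, 2), c(1, 1, 2, 1, 2, 2))
#' @export
nmi <- function(a, b) {
  ct <- confusion_table(a, b)
  N <- ct$total
  Nij <- ct$counts
  Ni <- ct$row_sums
  Nj <- ct$col_sums
  # log terms grouped so that the identity (A = B) and no-information
  # (single-community B) cases cancel exactly in floating point
  li <- log(Ni)[row(Nij)]
  lj <- log(Nj)[col(Nij)]
  pos <- Nij > 0
  num <- -2 * sum(Nij[pos] * ((log(Nij[pos]) - li[pos]) +
                                (log(N) - lj[pos])))
  den <- sum(Ni * (log(Ni) - log(N))) + sum(Nj * (log(Nj) - log(N)))
  if (den == 0) return(if (num == 0) 1 else 0)
  val <- num / den
  min(max(val, 0), 1)
}

#' Biggest-overlap matching between planted and retrieved communities
#'
#' Matches each planted community to the retrieved community with which it
#' shares the most nodes (ties broken toward the smaller retrieved label;
#' many-to-one matches allowed), then counts per planted community the
#' true positives (nodes in both), false positives (in the matched
#' retrieved community only), false negatives (in the planted community
#' only) and true negatives (in neither).
#'
#' @param planted,retrieved partitions of the same node set.
#' @return A data frame of class `match_result` with one row per planted
#'   community: `planted`, `matched`, `TP`, `FP`, `TN`, `FN`.
#' @export
match_communities <- function(planted, retrieved) {
  ct <- confusion_table(planted, retrieved)
  counts <- ct$counts
  N <- ct$total
  matched <- apply(counts, 1, which.max) # which.max takes the first (smallest label) tie
  TP <- counts[cbind(seq_len(nrow(counts)), matched)]
  FP <- ct$col_sums[matched] - TP
  FN <- ct$row_sums - TP
  TN <- N - TP - FP - FN
  structure(data.frame(planted = seq_len(nrow(counts)), matched = matched,
                       TP = TP, FP = FP, TN = TN, FN = FN),
            class = c("match_result", "data.frame"))
}

#' Sensitivity and specificity of a retrieved partition
#'
#' Per planted community, after biggest-overlap matching:
#' Sensitivity = TP / (TP + FN) and Specificity = TN / (TN + FP),
#' averaged (unweighted) over the planted communities. Both equal 1 for a
#' perfect match. A specificity denominator of 0 (matched and planted
#' communities jointly covering all nodes) is scored as 0.
#'
#' @inheritParams match_communities
#' @return A list with `sensitivity` and `specificity`, both in \[0, 1\].
#' @export
sensitivity_specificity <- function(planted, retrieved) {
  m <- match_communities(planted, retrieved)
  sens <- m$TP / (m$TP + m$FN)
  den <- m$TN + m$FP
  spec <- ifelse(den == 0, 0, m$TN / den)
  list(sensitivity = mean(sens), specificity = mean(spec))
}

#' Evaluate a retrieved partition against the planted ground truth
#'
#' @inheritParams match_communities
#' @return A one-row data frame with `nmi`, `sensitivity`, `specificity`.
#' @export
evaluate_partition <- function(planted, retrieved) {
  ss <- sensitivity_specificity(planted, retrieved)
  data.frame(nmi = nmi(planted, retrieved), sensitivity = ss$sensitivity,
             specificity = ss$specificity)
}
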