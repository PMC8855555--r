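# Split-selection metrics: Shannon entropy, information gain, split
# information, gain ratio (all base-2).

# binary entropy from counts, with 0 log 0 = 0
binary_entropy <- function(k, n) {
  if (n == 0) return(0)
  p <- k / n
  h <- 0
  if (p > 0) h <- h - p * log2(p)
  if (p < 1) h <- h - (1 - p) * log2(1 - p)
  h
}

#' Shannon entropy of a binary label set
#'
#' \eqn{-\sum_c p_c \log_2 p_c} over the two classes, with
#' \eqn{0 \log 0 = 0}; lies in \[0, 1\] for binary labels.
#'
#' @param labels Non-empty logical vector.
#' @return Entropy in bits.
#' @examples
#' entropy(c(TRUE, TRUE, FALSE, FALSE))        # 1
#' entropy(rep(c(TRUE, FALSE), c(2, 6)))       # 0.8113
#' @export
entropy <- function(labels) {
  if (!is.logical(labels) || length(labels) == 0L || anyNA(labels)) {
    stop_field("labels", "must be a non-empty logical vector")
  }
  binary_entropy(sum(labels), length(labels))
}

#' Information gain of a candidate partition
#'
#' Gain(S, A) = Entropy(S) - sum_j (|S_j|/|S|) Entropy(S_j): the drop in
#' label entropy from partitioning the parent set S into the branches S_j.
#' Always >= 0 and <= Entropy(S).
#'
#' @param parent_labels Logical vector of the parent set's labels.
#' @param branch_label_sets List of logical vectors that partition
#'   `parent_labels` (sizes and class counts must sum to the parent's).
#' @return Gain in bits.
#' @examples
#' parent <- rep(c(TRUE, FALSE), c(2, 6))
#' information_gain(parent, list(rep(c(TRUE, FALSE), c(2, 2)),
#'                               rep(FALSE, 4)))   # 0.3113
#' @export
information_gain <- function(parent_labels, branch_label_sets) {
  if (!is.logical(parent_labels) || length(parent_labels) == 0L) {
    stop_field("parent_labels", "must be a non-empty logical vector")
  }
  if (!is.list(branch_label_sets)) {
    stop_field("branch_label_sets", "must be a list of logical vectors")
  }
  sizes <- lengths(branch_label_sets)
  trues <- vapply(branch_label_sets, sum, numeric(1))
  n <- length(parent_labels)
  if (sum(sizes) != n || sum(trues) != sum(parent_labels)) {
    stop_field("branch_label_sets", "branches must partition the parent set")
  }
  h_parent <- binary_entropy(sum(parent_labels), n)
  h_children <- sum(vapply(seq_along(sizes), function(j) {
    sizes[j] / n * binary_entropy(trues[j], sizes[j])
  }, numeric(1)))
  max(h_parent - h_children, 0)
}

#' Split information of a partition
#'
#' The entropy of the branch-size distribution,
#' \eqn{-\sum_j (|S_j|/|S|) \log_2(|S_j|/|S|)}. Splits that send every
#' instance down one branch have split information 0 and are excluded as
#' split candidates (the gain ratio would divide by zero).
#'
#' @param branch_sizes Non-negative counts, at least one positive.
#' @return Split information in bits.
#' @examples
#' split_information(c(4, 4))   # 1
#' split_information(c(2, 6))   # 0.8113
#' @export
split_information <- function(branch_sizes) {
  if (!is.numeric(branch_sizes) || length(branch_sizes) == 0L ||
      any(branch_sizes < 0) || sum(branch_sizes) == 0) {
    stop_field("branch_sizes",
               "must be non-negative counts with a positive total")
  }
  n <- sum(branch_sizes)
  p <- branch_sizes[branch_sizes > 0] / n
  -sum(p * log2(p))
}

#' Gain ratio
#'
#' GainRatio(A) = Gain(S, A) / SplitInfo_A(S): information gain normalised
#' by the entropy of the branch sizes, the C4.5 criterion that discounts
#' attributes splitting the data into many small branches. A split
#' information of zero means the candidate does not actually divide the
#' data; such candidates are excluded upstream, and this function signals a
#' classed error (`aquarisk_degenerate_split`).
#'
#' @param gain Information gain, bits (>= 0).
#' @param split_info Split information, bits.
#' @return Dimensionless ratio.
#' @examples
#' gain_ratio(0.3113, 1.0)
#' @export
gain_ratio <- function(gain, split_info) {
  check_scalar_number(gain, "gain", nonneg = TRUE)
  check_scalar_number(split_info, "split_info", nonneg = TRUE)
  if (split_info == 0) {
    stop(structure(
      class = c("aquarisk_degenerate_split", "error", "condition"),
      list(message = "split information is 0: candidate excluded",
           call = sys.call(-1))
    ))
  }
  gain / split_info
}
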