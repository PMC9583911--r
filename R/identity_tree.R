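#' Gini impurity of a labeled sample set
#'
#' `Gini(D) = 1 - sum_k p_k^2` over the class proportions of `D`; 0 for a
#' pure set, approaching `1 - 1/|Y|` for a uniform mix of `|Y|` classes.
#'
#' @param labels vector of class labels (one per sample).
#' @return impurity in \[0, 1).
#' @export
gini <- function(labels) {
  if (length(labels) == 0) stop("empty sample set")
  p <- table(labels) / length(labels)
  1 - sum(p^2)
}

#' Branch-weighted Gini index of a threshold split
#'
#' Splits `D` into the samples whose RPKM for the attribute's fingerprint is
#' at or above the threshold and those below, and returns
#' `sum_v |D_v|/|D| * Gini(D_v)` over the two branches. The attribute whose
#' split minimizes this index is the individual to identify next.
#'
#' @param labels class labels of the current sample set.
#' @param rpkm matching RPKM values of one fingerprint.
#' @param threshold the fingerprint's fixed decision threshold.
#' @return weighted impurity.
#' @export
gini_index <- function(labels, rpkm, threshold) {
  if (length(labels) == 0) stop("empty sample set")
  if (length(rpkm) != length(labels)) stop("labels and rpkm lengths differ")
  if (is.na(threshold)) stop("threshold missing for attribute")
  above <- rpkm >= threshold
  g <- 0
  for (branch in list(above, !above)) {
    if (any(branch)) g <- g + mean(branch) * gini(labels[branch])
  }
  g
}

#' Build the fingerprint decision tree
#'
#' Greedy construction: at each node the remaining fingerprint attribute with
#' the smallest branch-weighted Gini index on the node's samples is selected;
#' samples at or above that fingerprint's threshold are committed to a leaf
#' labeled with its individual (impurity is reported, not re-split), and the
#' below branch recurses over the remaining attributes. When attributes are
#' exhausted the unlabeled leaf is attached, which is where out-of-cohort
#' samples end up. Thresholds are the fingerprints' fixed ROC-derived values;
#' the tree only chooses the order of the decisions. Gini ties break toward
#' the attribute with higher above-branch recall, then by individual_id.
#'
#' @param rpkm fingerprint x sample RPKM matrix for the training samples
#'   (rownames = individual_ids of the fingerprints).
#' @param labels named true individual per training sample.
#' @param thresholds named RPKM threshold per fingerprint individual.
#' @return an `identity_tree`: list of nodes (`kind`, `individual`,
#'   `threshold`, `above`, `below`, `n_train`, `precision`), node 1 the root.
#' @export
build_identity_tree <- function(rpkm, labels, thresholds) {
  inds <- rownames(rpkm)
  if (anyDuplicated(inds)) stop("duplicate fingerprints per individual")
  if (!all(inds %in% names(thresholds))) stop("threshold missing for attribute")
  labels <- labels[colnames(rpkm)]
  nodes <- list()
  add_node <- function(node) {
    nodes[[length(nodes) + 1L]] <<- node
    length(nodes)
  }
  grow <- function(sample_ids, remaining) {
    if (length(remaining) == 0) {
      return(add_node(list(kind = "unlabeled", individual = NA_character_,
                           threshold = NA_real_, above = NA_integer_,
                           below = NA_integer_,
                           n_train = length(sample_ids),
                           precision = NA_real_)))
    }
    lab <- labels[sample_ids]
    best <- NULL
    for (a in sort(remaining)) {
      v <- rpkm[a, sample_ids]
      gi <- if (length(sample_ids) > 0) gini_index(lab, v, thresholds[[a]]) else 0
      above <- sample_ids[v >= thresholds[[a]]]
      recall <- if (sum(lab == a) > 0) {
        sum(labels[above] == a) / sum(lab == a)
      } else 0
      cand <- list(a = a, gi = gi, recall = recall, above = above)
      if (is.null(best) || cand$gi < best$gi - 1e-12 ||
          (abs(cand$gi - best$gi) <= 1e-12 && cand$recall > best$recall + 1e-12)) {
        best <- cand
      }
    }
    below_ids <- setdiff(sample_ids, best$above)
    leaf_prec <- if (length(best$above) > 0) {
      mean(labels[best$above] == best$a)
    } else NA_real_
    leaf <- add_node(list(kind = "leaf", individual = best$a,
                          threshold = NA_real_, above = NA_integer_,
                          below = NA_integer_, n_train = length(best$above),
                          precision = leaf_prec))
    node_idx <- add_node(list(kind = "decision", individual = best$a,
                              threshold = thresholds[[best$a]],
                              above = leaf, below = NA_integer_,
                              n_train = length(sample_ids),
                              precision = leaf_prec))
    below_idx <- grow(below_ids, setdiff(remaining, best$a))
    nodes[[node_idx]]$below <<- below_idx
    node_idx
  }
  root <- grow(colnames(rpkm), inds)
  structure(list(nodes = nodes, root = root,
                 individuals = sort(inds)), class = "identity_tree")
}

#' Identify the donor of one sample
#'
#' Walks the tree: at each decision node the sample goes to that individual's
#' leaf when its fingerprint RPKM is at or above the threshold, otherwise on
#' to the next decision; samples exceeding no threshold reach the unlabeled
#' leaf.
#'
#' @param tree an `identity_tree`.
#' @param rpkm named RPKM vector over the tree's fingerprint individuals.
#' @return the individual_id, or `"unlabeled"`.
#' @export
identify_donor <- function(tree, rpkm) {
  missing <- setdiff(tree$individuals, names(rpkm))
  if (length(missing) > 0)
    stop("abundance missing for fingerprint(s): ",
         paste(missing, collapse = ", "))
  i <- tree$root
  repeat {
    node <- tree$nodes[[i]]
    if (node$kind == "unlabeled") return("unlabeled")
    if (node$kind == "leaf") return(node$individual)
    i <- if (rpkm[[node$individual]] >= node$threshold) node$above else node$below
  }
}

#' Evaluate the identifier on labeled samples
#'
#' @param tree an `identity_tree`.
#' @param rpkm fingerprint x sample RPKM matrix (rownames = individual_ids).
#' @param labels named true individual per sample.
#' @return list with `confusion` (rows = predicted incl. `"unlabeled"`,
#'   columns = true), `accuracy` (unlabeled in-cohort samples count as
#'   errors), and `per_individual` (precision/recall data frame).
#' @export
evaluate_identifier <- function(tree, rpkm, labels) {
  ids <- colnames(rpkm)
  if (length(ids) == 0) stop("empty test set")
  labels <- labels[ids]
  pred <- vapply(ids, function(s) identify_donor(tree, rpkm[, s]), "")
  truth_lv <- sort(unique(c(tree$individuals, labels)))
  pred_lv <- c(truth_lv, "unlabeled")
  confusion <- table(factor(pred, levels = pred_lv),
                     factor(labels, levels = truth_lv),
                     dnn = c("predicted", "true"))
  accuracy <- mean(pred == labels)
  per_ind <- data.frame(
    individual_id = truth_lv,
    precision = vapply(truth_lv, function(a) {
      np <- sum(pred == a)
      if (np == 0) NA_real_ else sum(pred == a & labels == a) / np
    }, 0),
    recall = vapply(truth_lv, function(a) {
      nt <- sum(labels == a)
      if (nt == 0) NA_real_ else sum(pred == a & labels == a) / nt
    }, 0),
    stringsAsFactors = FALSE)
  rownames(per_ind) <- NULL
  list(confusion = confusion, accuracy = accuracy, per_individual = per_ind,
       predicted = pred)
}

#' Serialize an identity tree to structured text
#'
#' One row per node: `node_id`, `kind`, `individual`, `threshold`, `above`,
#' `below`, `n_train`, `precision`.
#'
#' @param tree an `identity_tree`.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_identity_tree <- function(tree, path) {
  df <- data.frame(
    node_id = seq_along(tree$nodes),
    kind = vapply(tree$nodes, `[[`, "", "kind"),
    individual = vapply(tree$nodes, `[[`, "", "individual"),
    threshold = vapply(tree$nodes, `[[`, 0, "threshold"),
    above = vapply(tree$nodes, `[[`, 0L, "above"),
    below = vapply(tree$nodes, `[[`, 0L, "below"),
    n_train = vapply(tree$nodes, `[[`, 0L, "n_train"),
    precision = vapply(tree$nodes, `[[`, 0, "precision"),
    stringsAsFactors = FALSE)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("#identity_tree\troot=%d", tree$root), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an identity tree written by [write_identity_tree()]
#'
#' @param path TSV path.
#' @return an `identity_tree`.
#' @export
read_identity_tree <- function(path) {
  header <- readLines(path, n = 1L)
  m <- regmatches(header, regexec("^#identity_tree\troot=([0-9]+)$", header))[[1]]
  if (length(m) != 2) stop("not an identity tree file: ", path)
  df <- utils::read.delim(path, skip = 1L, stringsAsFactors = FALSE)
  nodes <- lapply(seq_len(nrow(df)), function(i) {
    list(kind = df$kind[i],
         individual = if (is.na(df$individual[i])) NA_character_
                      else df$individual[i],
         threshold = df$threshold[i],
         above = df$above[i], below = df$below[i],
         n_train = df$n_train[i], precision = df$precision[i])
  })
  inds <- sort(unique(df$individual[df$kind == "decision"]))
  structure(list(nodes = nodes, root = as.integer(m[2]), individuals = inds),
            class = "identity_tree")
}

#' @export
print.identity_tree <- function(x, ...) {
  cat("Fingerprint identity tree over ", length(x$individuals),
      " individuals\n", sep = "")
  i <- x$root
  depth <- 0
  while (!is.na(i)) {
    node <- x$nodes[[i]]
    pad <- strrep("  ", depth)
    if (node$kind == "unlabeled") {
      cat(pad, "-> unlabeled (out-of-cohort)\n", sep = "")
      break
    }
    cat(pad, "RPKM[", node$individual, "] >= ",
        format(node$threshold, digits = 5), " -> ", node$individual,
        if (!is.na(node$precision))
          sprintf(" (train precision %.2f)", node$precision) else "",
        "\n", sep = "")
    i <- node$below
    depth <- depth + 1
  }
  invisible(x)
}
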