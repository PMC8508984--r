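#' Balanced cross-validation folds
#'
#' Partitions the verified positives into k near-equal parts by a seeded
#' shuffle. For each fold, unverified (ncRNA, drug) pairs are sampled
#' uniformly without replacement, equal in count to the positives, and split
#' into a test negative set matching the fold's test positives and a train
#' negative set matching the remaining positives; within a fold the two
#' negative sets are disjoint and none overlaps any known positive.
#'
#' @param ds an [association_dataset].
#' @param k number of folds (>= 2).
#' @param seed integer seed; folds are reproducible from it.
#' @return A list of k folds, each a list with two-column index matrices
#'   `train_pos`, `test_pos`, `train_neg`, `test_neg`.
#' @export
make_folds <- function(ds, k, seed = 1L) {
  stopifnot(inherits(ds, "association_dataset"))
  k <- assert_count(k, "k", min = 2L)
  npos <- n_pairs(ds)
  if (npos < k) stop("fewer positives than folds", call. = FALSE)
  m <- n_ncrnas(ds); n <- n_drugs(ds)
  pos_lin <- (ds$pairs[, 1L] - 1L) * n + ds$pairs[, 2L]
  unverified <- setdiff(seq_len(m * n), pos_lin)
  if (length(unverified) < npos) {
    stop("not enough unverified pairs to sample balanced negatives",
         call. = FALSE)
  }

  with_seed(substream_seed(seed, "folds"), {
    perm <- sample.int(npos)
    sizes <- rep(npos %/% k, k)
    extra <- npos %% k
    if (extra > 0L) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
    fold_of <- rep(seq_len(k), times = sizes)

    lin_to_pairs <- function(lin) {
      cbind(ncrna = (lin - 1L) %/% n + 1L, drug = (lin - 1L) %% n + 1L)
    }
    lapply(seq_len(k), function(f) {
      test_idx <- perm[fold_of == f]
      neg_lin <- sample(unverified, npos)
      list(
        test_pos  = ds$pairs[test_idx, , drop = FALSE],
        train_pos = ds$pairs[-test_idx, , drop = FALSE],
        test_neg  = lin_to_pairs(neg_lin[seq_along(test_idx)]),
        train_neg = lin_to_pairs(neg_lin[-seq_along(test_idx)])
      )
    })
  })
}

#' Classification and ranking metrics
#'
#' Computes accuracy, precision = TP/(TP+FP), recall = TP/(TP+FN) and
#' F1 = 2PR/(P+R) at the thresholded prediction (positive when the score is
#' at least `threshold`), plus threshold-free AUC and AUPR. AUC uses the
#' rank statistic with mid-ranks for tied scores, which equals the
#' trapezoidal area under the ROC curve; AUPR is the non-interpolated
#' step integral of the precision-recall curve (ties processed as blocks).
#'
#' @param scores numeric prediction scores.
#' @param labels 0/1 ground-truth labels of the same length.
#' @param threshold decision threshold on the raw score; the default 0
#'   corresponds to logistic(score) >= 0.5.
#' @return A list with the six metrics and `roc` / `pr` curve data frames.
#' @export
compute_metrics <- function(scores, labels, threshold = 0) {
  if (length(scores) != length(labels)) {
    stop("scores and labels differ in length", call. = FALSE)
  }
  labels <- as.integer(labels)
  if (!all(labels %in% c(0L, 1L))) stop("labels must be 0/1", call. = FALSE)
  np <- sum(labels == 1L); nn <- sum(labels == 0L)
  if (np == 0L || nn == 0L) {
    stop("AUC undefined: labels contain a single class", call. = FALSE)
  }

  pred <- as.integer(scores >= threshold)
  TP <- sum(pred == 1L & labels == 1L)
  FP <- sum(pred == 1L & labels == 0L)
  TN <- sum(pred == 0L & labels == 0L)
  FN <- sum(pred == 0L & labels == 1L)
  accuracy <- (TP + TN) / (TP + TN + FP + FN)
  precision <- if (TP + FP > 0L) TP / (TP + FP) else 0
  recall <- TP / (TP + FN)
  f1 <- if (precision + recall > 0) {
    2 * precision * recall / (precision + recall)
  } else {
    warning("precision + recall = 0; F1 set to 0")
    0
  }

  r <- rank(scores, ties.method = "average")
  auc <- (sum(r[labels == 1L]) - np * (np + 1) / 2) / (np * nn)

  # group tied scores, descending
  ord <- order(scores, decreasing = TRUE)
  s_ord <- scores[ord]; l_ord <- labels[ord]
  grp <- cumsum(!duplicated(s_ord))
  tp_g <- tapply(l_ord, grp, sum)
  n_g <- tabulate(grp)
  tp_cum <- cumsum(tp_g)
  all_cum <- cumsum(n_g)
  fp_cum <- all_cum - tp_cum

  roc <- data.frame(fpr = c(0, fp_cum / nn), tpr = c(0, tp_cum / np))
  prec_cum <- tp_cum / all_cum
  rec_cum <- tp_cum / np
  aupr <- sum((tp_g / np) * prec_cum)
  pr <- data.frame(recall = c(0, rec_cum), precision = c(1, prec_cum))

  list(auc = auc, aupr = aupr, accuracy = accuracy, precision = precision,
       recall = recall, f1 = f1, roc = roc, pr = pr,
       confusion = c(TP = TP, FP = FP, TN = TN, FN = FN))
}

#' k-fold cross-validated evaluation
#'
#' For each fold a fresh model is trained on the fold's training positives
#' only; BPR negative sampling is barred from every known positive and from
#' the fold's test pairs (positives and negatives alike), so no test
#' information leaks into training. The trained model scores the balanced
#' test set and the six metrics are accumulated per fold and averaged.
#'
#' @param ds an [association_dataset].
#' @param hp a [hyperparameters()] object.
#' @param k number of folds.
#' @param seed integer seed driving fold assignment and per-fold training.
#' @return A `linkgcn_eval` report: `per_fold` data frame, `averages` named
#'   vector, and per-fold ROC/PR `curves`.
#' @export
cross_validate <- function(ds, hp = hyperparameters(), k = 5L, seed = 1L) {
  folds <- make_folds(ds, k, seed = seed)
  per_fold <- vector("list", length(folds))
  curves <- vector("list", length(folds))
  for (f in seq_along(folds)) {
    fold <- folds[[f]]
    train_ds <- association_dataset(ds$ncrnas, ds$drugs, fold$train_pos)
    hp_f <- hp
    hp_f$seed <- substream_seed(seed, sprintf("fold%02d", f))
    model <- train_model(
      train_ds, hp_f,
      forbidden_pairs = rbind(fold$test_pos, fold$test_neg)
    )
    test_pairs <- rbind(fold$test_pos, fold$test_neg)
    scores <- score_pairs(model, test_pairs)
    labels <- rep(c(1L, 0L), c(nrow(fold$test_pos), nrow(fold$test_neg)))
    met <- compute_metrics(scores, labels)
    per_fold[[f]] <- data.frame(
      fold = f, auc = met$auc, aupr = met$aupr, accuracy = met$accuracy,
      precision = met$precision, recall = met$recall, f1 = met$f1
    )
    curves[[f]] <- list(roc = met$roc, pr = met$pr)
  }
  per_fold <- do.call(rbind, per_fold)
  averages <- colMeans(per_fold[, -1L])
  structure(
    list(per_fold = per_fold, averages = averages, curves = curves,
         k = k, seed = seed),
    class = "linkgcn_eval"
  )
}

#' @export
print.linkgcn_eval <- function(x, ...) {
  cat(sprintf("<linkgcn_eval> %d-fold cross-validation\n", x$k))
  tab <- rbind(x$per_fold[, -1L], Avg. = x$averages)
  rownames(tab) <- c(as.character(x$per_fold$fold), "Avg.")
  print(round(tab, 4))
  invisible(x)
}

#' Rank candidate ncRNAs for a drug
#'
#' Removes the ncRNAs already known to be associated with the query drug and
#' sorts the remaining ones by descending predicted score (ties broken by
#' ascending ncRNA index, so the ordering is deterministic). This is the
#' screening procedure used to nominate novel resistance-associated ncRNAs
#' for a drug of interest.
#'
#' @param state a trained, propagated `linkgcn_model`.
#' @param ds the [association_dataset] the model was trained on (supplies
#'   the known associations to exclude).
#' @param drug_id drug label, matched against the vocabulary.
#' @param top_n number of candidates to return (default 15, the usual
#'   case-study shortlist size); a larger request returns the full pool.
#' @return A data frame with columns `rank`, `ncrna`, `score`.
#' @export
rank_candidates <- function(state, ds, drug_id, top_n = 15L) {
  stopifnot(inherits(state, "linkgcn_model"),
            inherits(ds, "association_dataset"))
  top_n <- assert_count(top_n, "top_n")
  j <- match(drug_id, ds$drugs)
  if (is.na(j)) {
    near <- utils::head(ds$drugs[order(utils::adist(drug_id, ds$drugs))], 3L)
    stop(sprintf("unknown drug '%s'; nearest labels: %s",
                 drug_id, paste(near, collapse = ", ")), call. = FALSE)
  }
  known <- ds$pairs[ds$pairs[, 2L] == j, 1L]
  candidates <- setdiff(seq_len(n_ncrnas(ds)), known)
  if (length(candidates) == 0L) {
    return(data.frame(rank = integer(0), ncrna = character(0),
                      score = numeric(0)))
  }
  s <- score_pairs(state, cbind(candidates, j))
  ord <- order(-s, candidates)
  keep <- utils::head(ord, top_n)
  data.frame(
    rank = seq_along(keep),
    ncrna = ds$ncrnas[candidates[keep]],
    score = s[keep]
  )
}
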