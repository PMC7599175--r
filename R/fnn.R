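## Step 2 of the predictor: an ensemble of single-hidden-layer feed-forward
## networks. The zone members are split into 4 stratified folds; for each
## fold k a "type" of 100 networks is trained on the other three folds
## (differing only in their random initialisation). A type votes "delayed"
## by majority of its networks; the final call is a two-vote aggregation
## over the four types. Networks are fitted with nnet (softmax outputs,
## weight decay, BFGS), which satisfies the determinism and probability
## contracts required here.

#' Network training specification
#'
#' @param n_hidden Hidden-layer width; default `NULL` means number of
#'   inputs + 1.
#' @param activation Hidden-unit transfer function. Only `"logistic"` is
#'   supported by the underlying trainer.
#' @param max_epochs Optimiser iteration cap (default 200).
#' @param decay Weight-decay penalty regularising each network in place of
#'   validation-based early stopping (default 5e-4).
#' @param class_weighting Re-weight the delayed class inversely to its
#'   prevalence among the training members (default `TRUE`).
#' @return An `fnn_spec` list.
#' @export
fnn_spec <- function(n_hidden = NULL, activation = "logistic",
                     max_epochs = 200L, decay = 5e-4,
                     class_weighting = TRUE) {
  if (!identical(activation, "logistic"))
    stop("only logistic hidden units are supported by the trainer")
  if (!is.null(n_hidden))
    stopifnot(is.numeric(n_hidden), n_hidden >= 1, n_hidden == round(n_hidden))
  stopifnot(is.numeric(max_epochs), max_epochs >= 1,
            is.numeric(decay), decay >= 0)
  structure(list(n_hidden = if (!is.null(n_hidden)) as.integer(n_hidden),
                 activation = activation,
                 max_epochs = as.integer(max_epochs), decay = decay,
                 class_weighting = isTRUE(class_weighting)),
            class = "fnn_spec")
}

#' Stratified fold assignment
#'
#' Delayed and non-delayed subjects are distributed across folds
#' separately, so every fold carries its share of the rare class.
#'
#' @param labels 0/1 outcome labels.
#' @param k Number of folds.
#' @return Integer fold index in 1..k per subject. Must be called inside an
#'   established RNG state (the caller seeds).
#' @export
stratified_folds <- function(labels, k = 4L) {
  fold <- integer(length(labels))
  for (cls in unique(labels)) {
    idx <- which(labels == cls)
    fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
  }
  fold
}

#' Train the cross-validated network ensemble
#'
#' @param members Cohort table restricted to the DDCRZ members (step-1
#'   survivors); every subject must have complete values on the inner
#'   subset.
#' @param selection A [select_characteristics()] result; its `inner_subset`
#'   defines the network inputs.
#' @param spec An [fnn_spec()].
#' @param seed Integer seed governing fold assignment and all network
#'   initialisations; identical `(spec, seed)` gives identical vote records
#'   on any input.
#' @param n_folds Number of folds / network types (default 4).
#' @param nets_per_type Networks per type (default 100).
#' @param vote_threshold_final Number of type votes required for a final
#'   "delayed" call (default 2).
#' @param fold_assignment Optional pre-computed fold index per member row
#'   (used by the pipeline to share folds with the zone-fitting stage);
#'   default is a seeded stratified split.
#' @param train_member_mask Optional logical `nrow(members) x n_folds`
#'   matrix; type `k` trains only on rows of folds != k with
#'   `train_member_mask[, k]` `TRUE`. This is how the pipeline restricts
#'   each type to the members of its own leak-free zone fit.
#' @return An `ensemble_predictor`.
#' @export
train_ensemble <- function(members, selection, spec = fnn_spec(), seed = 1L,
                           n_folds = 4L, nets_per_type = 100L,
                           vote_threshold_final = 2L,
                           fold_assignment = NULL,
                           train_member_mask = NULL) {
  stopifnot(inherits(selection, "selection_result"),
            inherits(spec, "fnn_spec"),
            n_folds >= 2L, nets_per_type >= 1L,
            vote_threshold_final >= 1L, vote_threshold_final <= n_folds)
  inner <- selection$inner_subset
  if (!length(inner)) stop("selection has an empty inner subset")
  x <- as.matrix(members[, inner, drop = FALSE])
  if (anyNA(x))
    stop("members must have complete values on the inner subset; ",
         "incomplete subjects are excluded at step 1")
  lab <- as.integer(members$label)
  n <- nrow(x)
  if (n < 8L || sum(lab) < 4L)
    stop("need at least 8 zone members including at least 4 delayed ",
         "to stratify ", n_folds, " folds (have ", n, " members, ",
         sum(lab), " delayed)")
  if (is.null(train_member_mask))
    train_member_mask <- matrix(TRUE, n, n_folds)
  stopifnot(is.matrix(train_member_mask),
            nrow(train_member_mask) == n, ncol(train_member_mask) == n_folds)

  set.seed(as.integer(seed) %% .Machine$integer.max)
  if (is.null(fold_assignment)) fold_assignment <- stratified_folds(lab, n_folds)
  stopifnot(length(fold_assignment) == n,
            all(fold_assignment %in% seq_len(n_folds)))
  net_seeds <- matrix(sample.int(.Machine$integer.max,
                                 n_folds * nets_per_type),
                      n_folds, nets_per_type)

  n_hidden <- spec$n_hidden %||% (length(inner) + 1L)
  types <- vector("list", n_folds)
  for (k in seq_len(n_folds)) {
    tr <- fold_assignment != k & train_member_mask[, k]
    if (sum(lab[tr]) == 0L)
      stop("fold ", k, " leaves no delayed subject in its training split; ",
           "use fewer folds or more data")
    if (sum(lab[tr] == 0L) == 0L)
      stop("fold ", k, " leaves no non-delayed subject in its training split")
    xtr <- x[tr, , drop = FALSE]
    center <- colMeans(xtr)
    scale <- apply(xtr, 2, stats::sd)
    scale[!is.finite(scale) | scale == 0] <- 1
    xs <- sweep(sweep(xtr, 2, center), 2, scale, `/`)
    ytr <- cbind(normal = 1 - lab[tr], delayed = lab[tr])
    w <- rep(1, sum(tr))
    if (spec$class_weighting) {
      nd <- sum(lab[tr]); nn <- sum(1 - lab[tr])
      w <- ifelse(lab[tr] == 1L, sum(tr) / (2 * nd), sum(tr) / (2 * nn))
    }
    nets <- vector("list", nets_per_type)
    for (i in seq_len(nets_per_type)) {
      set.seed(net_seeds[k, i])
      nets[[i]] <- nnet::nnet(xs, ytr, size = n_hidden, softmax = TRUE,
                              decay = spec$decay, maxit = spec$max_epochs,
                              weights = w, trace = FALSE)
    }
    types[[k]] <- list(nets = nets, center = center, scale = scale,
                       n_train = sum(tr), n_train_delayed = sum(lab[tr]))
  }
  structure(list(inner_subset = inner, fold_assignment = fold_assignment,
                 subject_id = members$subject_id,
                 n_folds = as.integer(n_folds),
                 nets_per_type = as.integer(nets_per_type),
                 vote_threshold_final = as.integer(vote_threshold_final),
                 spec = spec, n_hidden = n_hidden, types = types),
            class = "ensemble_predictor")
}

#' @export
print.ensemble_predictor <- function(x, ...) {
  cat("fNN ensemble: ", x$n_folds, " types x ", x$nets_per_type,
      " networks (", x$n_hidden, " hidden units), inputs: ",
      paste(x$inner_subset, collapse = ", "), "\n", sep = "")
  cat("  final vote: delayed when >= ", x$vote_threshold_final, " of ",
      x$n_folds, " type votes are delayed\n", sep = "")
  invisible(x)
}

#' Combine per-type delayed counts into type and final votes
#'
#' A type votes delayed when at least half of its networks do (an exact
#' 50/50 split counts as delayed, favouring sensitivity); the final call is
#' delayed when at least `final_threshold` types vote delayed.
#'
#' @param counts Integer vector (or matrix, subjects x types) of
#'   delayed-voting network counts per type.
#' @param n_nets Networks per type.
#' @param final_threshold Type votes required for a final delayed call.
#' @return List with `type_votes` (0/1, same shape as `counts`) and `final`
#'   (0/1 per subject).
#' @export
aggregate_votes <- function(counts, n_nets, final_threshold = 2L) {
  type_votes <- (2L * counts >= n_nets) * 1L
  final <- if (is.matrix(type_votes)) (rowSums(type_votes) >= final_threshold) * 1L
           else (sum(type_votes) >= final_threshold) * 1L
  list(type_votes = type_votes, final = final)
}

ensemble_counts <- function(object, newdata) {
  x <- as.matrix(newdata[, object$inner_subset, drop = FALSE])
  if (anyNA(x)) {
    bad <- object$inner_subset[colSums(is.na(x)) > 0][1]
    stop("missing value for inner characteristic ", bad,
         "; incomplete subjects must be routed out at step 1")
  }
  counts <- matrix(0L, nrow(x), object$n_folds)
  for (k in seq_len(object$n_folds)) {
    ty <- object$types[[k]]
    xs <- sweep(sweep(x, 2, ty$center), 2, ty$scale, `/`)
    votes <- integer(nrow(x))
    for (net in ty$nets) {
      p <- stats::predict(net, xs)
      votes <- votes + (p[, "delayed"] >= 0.5)  # tie counts as delayed
    }
    counts[, k] <- votes
  }
  counts
}

#' Predict with the ensemble
#'
#' @param object An [train_ensemble()] result.
#' @param newdata Cohort table (or data frame) with complete inner-subset
#'   values.
#' @param type `"record"` for the full vote record, `"final"` for the 0/1
#'   final vote only.
#' @param ... Unused.
#' @return `"record"`: data frame with per-type delayed counts
#'   (`count_1..`), per-type binary votes (`vote_1..`) and `final`;
#'   `"final"`: integer vector.
#' @export
predict.ensemble_predictor <- function(object, newdata,
                                       type = c("record", "final"), ...) {
  type <- match.arg(type)
  counts <- ensemble_counts(object, newdata)
  agg <- aggregate_votes(counts, object$nets_per_type,
                         object$vote_threshold_final)
  if (type == "final") return(agg$final)
  rec <- data.frame(counts, agg$type_votes, final = agg$final)
  names(rec) <- c(paste0("count_", seq_len(object$n_folds)),
                  paste0("vote_", seq_len(object$n_folds)), "final")
  if (!is.null(newdata$subject_id))
    rec <- cbind(subject_id = newdata$subject_id, rec)
  rec
}

#' Out-of-fold type vote per training member
#'
#' Each member is judged only by the type whose training folds exclude it —
#' the honest generalisation measure for the member set itself.
#'
#' @param object An [train_ensemble()] result.
#' @param members The member table the ensemble was trained on (same row
#'   order).
#' @return 0/1 vector: the member's own-fold type vote.
#' @export
predict_oof <- function(object, members) {
  stopifnot(nrow(members) == length(object$fold_assignment))
  counts <- ensemble_counts(object, members)
  votes <- (2L * counts >= object$nets_per_type) * 1L
  votes[cbind(seq_len(nrow(votes)), object$fold_assignment)]
}

#' Full two-step prediction
#'
#' Step 1: subjects outside the DDCRZ are classified as normally developing;
#' subjects with a missing zone characteristic are excluded. Step 2: zone
#' members receive the ensemble's final vote.
#'
#' @param table Cohort table.
#' @param zones A [build_ddcrz()] result.
#' @param ensemble An [train_ensemble()] result.
#' @return Character vector per subject: `"delayed"`, `"normal"` or
#'   `"excluded_incomplete"`.
#' @export
predict_two_step <- function(table, zones, ensemble) {
  membership <- zone_membership_table(table, zones)
  out <- rep("normal", nrow(table))
  out[membership == "incomplete"] <- "excluded_incomplete"
  mem <- membership == "member"
  if (any(mem)) {
    final <- predict(ensemble, table[mem, , drop = FALSE], type = "final")
    out[mem] <- ifelse(final == 1L, "delayed", "normal")
  }
  out
}
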