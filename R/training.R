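# Dataset filters, cluster-level splitting, the binary cross-entropy loss
# and the training loop.

#' Training subunit filter
#'
#' A subunit enters training when it has at most `max_atoms` heavy atoms
#' (the memory cap, roughly 100 kDa) and at least `min_residues` amino
#' acids.  Both boundaries are inclusive on the allowed side: exactly 8192
#' atoms passes, 47 amino acids does not.
#'
#' @param structure an [atomic_structure()].
#' @param max_atoms heavy-atom cap (default 8192).
#' @param min_residues amino-acid floor (default 48).
#' @param cats molecule catalogue (amino-acid list).
#' @return named logical vector, one entry per subunit.
#' @export
filter_training_subunit <- function(structure, max_atoms = 8192L,
                                    min_residues = 48L,
                                    cats = default_molecule_categories()) {
  out <- logical(length(structure$subunits))
  names(out) <- names(structure$subunits)
  res_of_atom <- structure$atoms$res_idx
  sub_of_res <- residue_subunit_map(structure)
  for (s in seq_along(structure$subunits)) {
    ri <- structure$subunits[[s]]
    natom <- sum(sub_of_res[res_of_atom] == s)
    naa <- sum(structure$residues$name[ri] %in% cats$amino_acids)
    out[s] <- natom <= max_atoms && naa >= min_residues
  }
  out
}

#' Assign sequence-identity clusters to train/valid/test splits
#'
#' Whole clusters are assigned (no chain of a cluster ever straddles two
#' splits) by a seeded greedy best-fit: clusters are visited in random
#' order and each goes to the split with the largest remaining chain-count
#' deficit relative to its target fraction.
#'
#' @param clusters data.frame with columns `chain_id`, `cluster_id`
#'   (externally produced, e.g. at 30 percent sequence identity).
#' @param fractions named numeric vector `c(train=, valid=, test=)` summing
#'   to 1 (default 0.70/0.15/0.15).
#' @param seed RNG seed; the same seed always yields the same assignment.
#' @return data.frame `chain_id`, `cluster_id`, `split`.
#' @export
assign_splits <- function(clusters,
                          fractions = c(train = 0.70, valid = 0.15,
                                        test = 0.15),
                          seed = 1L) {
  stopifnot(all(c("chain_id", "cluster_id") %in% names(clusters)))
  if (abs(sum(fractions) - 1) > 1e-8) stop("fractions must sum to 1")
  ids <- unique(clusters$cluster_id)
  if (length(ids) < 3L) stop("need at least 3 clusters to split")
  sizes <- table(factor(clusters$cluster_id, levels = ids))
  total <- sum(sizes)
  target <- fractions * total
  assigned <- stats::setNames(numeric(length(fractions)), names(fractions))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  order_ids <- sample(ids)
  split_of <- stats::setNames(character(length(ids)), ids)
  for (cid in order_ids) {
    deficit <- target - assigned
    pick <- names(fractions)[which.max(deficit)]
    split_of[cid] <- pick
    assigned[pick] <- assigned[pick] + sizes[[cid]]
  }
  data.frame(chain_id = clusters$chain_id,
             cluster_id = clusters$cluster_id,
             split = unname(split_of[as.character(clusters$cluster_id)]),
             stringsAsFactors = FALSE)
}

#' Binary cross-entropy loss over residues and channels
#'
#' Mean per-channel BCE with predictions clamped to `[eps, 1 - eps]`;
#' optional positive-class weights per channel rescale the contribution of
#' positive labels.
#'
#' @param pred numeric matrix (residues x channels) of confidences, or a
#'   [prediction_result()].
#' @param labels binary matrix of the same shape, or an `interface_labels`
#'   object (its channels are matched against the prediction channels).
#' @param weights optional positive-class weight per channel (default 1).
#' @param eps clamping constant (default 1e-7).
#' @return scalar loss.
#' @export
compute_loss <- function(pred, labels, weights = NULL, eps = 1e-7) {
  if (inherits(pred, "prediction_result")) {
    pred <- as.matrix(as.data.frame(pred)[attr(pred, "channels")])
  }
  if (inherits(labels, "interface_labels")) {
    lab <- labels$labels[, colnames(pred), drop = FALSE]
  } else {
    lab <- labels
  }
  if (!all(dim(pred) == dim(lab))) stop("prediction/label shape mismatch")
  if (is.null(weights)) weights <- rep(1, ncol(pred))
  p <- pmin(pmax(pred, eps), 1 - eps)
  w <- matrix(weights, nrow(p), ncol(p), byrow = TRUE)
  mean(-(w * lab * log(p) + (1 - lab) * log(1 - p)))
}

#' Training configuration
#'
#' @param lr Adam learning rate.
#' @param epochs passes over the training set.
#' @param seed shuffling/initialisation seed.
#' @param pos_weight `"balanced"` (per-channel `n_neg / n_pos` computed on
#'   the training labels, capped at `pos_weight_cap`), a numeric vector, or
#'   `NULL` for unweighted.
#' @param pos_weight_cap cap for balanced weights.
#' @param clip global gradient-norm clip (`NULL` to disable).
#' @param max_atoms,min_residues training filters (see
#'   [filter_training_subunit()]).
#' @return a `train_config` list.
#' @export
train_config <- function(lr = 1e-3, epochs = 4L, seed = 1L,
                         pos_weight = "balanced", pos_weight_cap = 10,
                         clip = 100, max_atoms = 8192L, min_residues = 48L) {
  stopifnot(lr >= 0, epochs >= 0)
  structure(as.list(environment()), class = "train_config")
}

# align a labels object to the protein rows of a featurized structure
align_labels <- function(labels, feats, channels) {
  stopifnot(identical(labels$residue_index, feats$protein_rows))
  labels$labels[, channels, drop = FALSE]
}

#' Train a model on a corpus of labelled structures
#'
#' Stochastic training: one structure per optimizer step, Adam updates,
#' per-channel class-weighted binary cross-entropy on the protein residues.
#' Structures failing the training filters are dropped up front.  Training
#' aborts with a diagnostic if the loss turns non-finite.
#'
#' @param params a `model_params` from [build_model()].
#' @param structures list of [atomic_structure()].
#' @param labels list of `interface_labels` (generator truth or
#'   [label_interfaces()] output), aligned with `structures`.
#' @param config a [train_config()].
#' @param quiet suppress per-epoch messages.
#' @return list with `params` (trained), `log` (data.frame of per-epoch
#'   mean training loss) and `pos_weight` (the weights used).
#' @export
train_model <- function(params, structures, labels,
                        config = train_config(), quiet = TRUE) {
  mconf <- params$config
  channels <- mconf$channels
  keep <- vapply(structures, function(st)
    all(filter_training_subunit(st, config$max_atoms, config$min_residues)[
      categorize_subunits(st) == "protein"]), TRUE)
  structures <- structures[keep]
  labels <- labels[keep]
  if (length(structures) == 0L) stop("no structures pass the training filters")

  feats <- lapply(structures, featurize_structure, config = mconf)
  labmats <- Map(align_labels, labels, feats,
                 MoreArgs = list(channels = channels))

  w <- rep(1, length(channels))
  if (identical(config$pos_weight, "balanced")) {
    all_lab <- do.call(rbind, labmats)
    npos <- pmax(colSums(all_lab), 1)
    w <- pmin((nrow(all_lab) - npos) / npos, config$pos_weight_cap)
    w <- pmax(w, 1)
  } else if (is.numeric(config$pos_weight)) {
    w <- rep(config$pos_weight, length.out = length(channels))
  }

  weights <- params[c("embed", "blocks", "pool", "head")]
  opt <- adam_init(weights)
  set.seed(config$seed)
  log_rows <- list()
  eps <- 1e-7
  for (ep in seq_len(config$epochs)) {
    ord <- sample(seq_along(feats))
    losses <- numeric(length(ord))
    for (k in seq_along(ord)) {
      i <- ord[k]
      tp <- ad_tape()
      leaves <- ad_leaves(tp, weights)
      conf <- model_forward(tp, leaves, feats[[i]], mconf)
      rows <- feats[[i]]$protein_rows
      lab <- labmats[[i]]
      pnode <- ad_clamp(tp, ad_gather(tp, conf, rows), eps, 1 - eps)
      wm <- matrix(w, nrow(lab), ncol(lab), byrow = TRUE)
      one <- matrix(1, nrow(lab), ncol(lab))
      t1 <- ad_mul(tp, ad_log(tp, pnode), -wm * lab)
      t2 <- ad_mul(tp, ad_log(tp, ad_sub(tp, one, pnode)), -(1 - lab))
      loss <- ad_scale(tp, ad_sum(tp, ad_add(tp, t1, t2)),
                       1 / length(lab))
      lv <- nval(loss)
      if (!is.finite(lv)) {
        stop(sprintf("training diverged (non-finite loss at epoch %d, step %d)",
                     ep, k))
      }
      losses[k] <- lv
      if (config$lr > 0) {
        grads <- ad_read_grads(ad_backward(tp, loss),
                               leaves[c("embed", "blocks", "pool", "head")])
        step <- adam_step(weights, grads, opt, lr = config$lr,
                          clip = config$clip)
        weights <- step$params
        opt <- step$state
      }
    }
    log_rows[[ep]] <- data.frame(epoch = ep, loss = mean(losses))
    if (!quiet) message(sprintf("epoch %d: loss %.4f", ep, mean(losses)))
  }
  out <- params
  out[c("embed", "blocks", "pool", "head")] <- weights
  list(params = out,
       log = if (length(log_rows)) do.call(rbind, log_rows) else
         data.frame(epoch = integer(0), loss = numeric(0)),
       pos_weight = w)
}
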