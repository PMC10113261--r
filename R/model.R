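# Full architecture: element embedding -> stacked geometric transformer
# blocks with a growing neighbourhood schedule -> residue pooling -> MLP
# head with sigmoid confidences.

#' Model configuration
#'
#' The default configuration matches the published architecture: state size
#' 32, a 3-layer embedding of the element one-hot, 4 sets of 8 transformer
#' blocks with neighbourhoods growing through nn = 8, 16, 32, 64, key width
#' 3 with 2 attention heads per block, 4-head residue pooling, and a
#' 3-layer decoding MLP.
#'
#' @param S state size (scalar and vector channels per atom).
#' @param nn_schedule list of `c(block_count, nn)` pairs; nn values must be
#'   positive and non-decreasing.
#' @param n_key attention key width.
#' @param n_head_atom attention heads in each transformer block.
#' @param n_head_pool heads of the residue pooling attention.
#' @param channels ordered interface-category names to predict.
#' @param vocab element vocabulary (one-hot width is `length(vocab) + 1`).
#' @return a `model_config` list.
#' @export
model_config <- function(S = 32L,
                         nn_schedule = list(c(8L, 8L), c(8L, 16L),
                                            c(8L, 32L), c(8L, 64L)),
                         n_key = 3L, n_head_atom = 2L, n_head_pool = 4L,
                         channels = interface_channels(),
                         vocab = default_element_vocab()) {
  if (length(nn_schedule) == 0L) stop("nn_schedule must be non-empty")
  nns <- vapply(nn_schedule, function(x) x[2L], 0)
  cnt <- vapply(nn_schedule, function(x) x[1L], 0)
  if (any(nns <= 0) || any(cnt <= 0)) stop("invalid nn_schedule")
  if (is.unsorted(nns)) stop("nn values must be non-decreasing")
  if (length(channels) == 0L) stop("channels must be non-empty")
  structure(list(S = as.integer(S), nn_schedule = nn_schedule,
                 n_key = as.integer(n_key),
                 n_head_atom = as.integer(n_head_atom),
                 n_head_pool = as.integer(n_head_pool),
                 channels = channels, vocab = vocab),
            class = "model_config")
}

# blocks as a flat integer vector of nn values, one per block
schedule_nns <- function(config) {
  unlist(lapply(config$nn_schedule, function(x) rep(as.integer(x[2L]), x[1L])))
}

#' Build a model (initialise parameters)
#'
#' Deterministic for a given seed: the same seed yields bit-identical
#' parameters.
#'
#' @param config a [model_config()].
#' @param seed integer RNG seed.
#' @return a `model_params` list: `embed`, `blocks` (one set of layer
#'   parameters per transformer block), `pool`, `head`, and `config`.
#' @export
build_model <- function(config = model_config(), seed = 1L) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  S <- config$S
  nns <- schedule_nns(config)
  params <- list(
    embed = nn_init_mlp(c(length(config$vocab) + 1L, S, S, S)),
    blocks = lapply(seq_along(nns), function(b)
      init_layer_params(S, config$n_key, config$n_head_atom)),
    pool = init_pool_params(S, config$n_head_pool),
    head = init_head_params(S, length(config$channels)),
    config = config
  )
  class(params) <- "model_params"
  params
}

#' @export
print.model_params <- function(x, ...) {
  cat(sprintf("<model_params> S=%d, %d blocks (nn: %s), %d channels\n",
              x$config$S, length(x$blocks),
              paste(unique(schedule_nns(x$config)), collapse = ","),
              length(x$config$channels)))
  invisible(x)
}

# ---- featurization cache ------------------------------------------------

# Everything the forward pass needs from a structure, computed once:
# element one-hot, flattened kNN graphs per distinct nn, atom->residue map,
# and the protein-residue rows to report.
featurize_structure <- function(structure, config,
                                cats = default_molecule_categories(),
                                include_context = TRUE) {
  categories <- categorize_subunits(structure, cats)
  if (!any(categories == "protein")) stop("no protein subunit in structure")
  sub_of_res <- residue_subunit_map(structure)
  keep_res <- if (include_context) {
    seq_len(n_residues(structure))
  } else {
    sort(unlist(structure$subunits[categories == "protein"], use.names = FALSE))
  }
  st <- if (length(keep_res) == n_residues(structure)) structure else
    subset_structure(structure, keep_res)
  categories_kept <- categorize_subunits(st, cats)
  sub_kept <- residue_subunit_map(st)
  prot_res <- unname(which(categories_kept[sub_kept] == "protein"))
  coords <- atom_coords(st)
  graphs <- lapply(unique(schedule_nns(config)), function(nn)
    flatten_graph(build_knn_graph(coords, nn)))
  names(graphs) <- as.character(unique(schedule_nns(config)))
  list(onehot = encode_elements(st, config$vocab),
       graphs = graphs,
       res_of_atom = st$atoms$res_idx,
       n_res = n_residues(st),
       protein_rows = prot_res,
       structure = st)
}

# tape-level full forward; returns residue confidence node (all residues)
model_forward <- function(tp, leaves, feats, config) {
  q <- nn_mlp(tp, leaves$embed, feats$onehot)
  n <- nrow(feats$onehot)
  states <- list(q = q, P = matrix(0, n, 3L * config$S))
  nns <- schedule_nns(config)
  for (b in seq_along(nns)) {
    fg <- feats$graphs[[as.character(nns[b])]]
    states <- tf_block(tp, states, fg, leaves$blocks[[b]],
                       config$n_key, config$n_head_atom)
  }
  pooled <- tf_pool(tp, states, feats$res_of_atom, feats$n_res,
                    leaves$pool, config$n_head_pool)
  tf_head(tp, pooled, leaves$head)
}

#' Predict per-residue interface confidences
#'
#' Runs the full network on a cleaned structure.  Non-protein subunits
#' (ions, ligands, nucleic acids present in the file) are included as
#' geometric context by default but only protein residues are scored.
#'
#' @param object a `model_params` object from [build_model()] or
#'   [train_model()].
#' @param structure an [atomic_structure()].
#' @param include_context include non-protein atoms in the point cloud.
#' @param cats molecule catalogue for subunit categorization.
#' @param ... unused.
#' @return a [prediction_result()] with one row per protein residue and one
#'   confidence column per channel.
#' @export
predict.model_params <- function(object, structure, include_context = TRUE,
                                 cats = default_molecule_categories(), ...) {
  config <- object$config
  feats <- featurize_structure(structure, config, cats, include_context)
  tp <- ad_tape()
  conf <- nval(model_forward(tp, object, feats, config))
  rows <- feats$protein_rows
  st <- feats$structure
  tab <- data.frame(chain_tag = st$residues$chain_tag[rows],
                    author_number = st$residues$author_number[rows],
                    residue_name = st$residues$name[rows],
                    stringsAsFactors = FALSE)
  for (ci in seq_along(config$channels)) tab[[config$channels[ci]]] <- conf[rows, ci]
  prediction_result(tab, config$channels)
}

#' Predict over an ensemble of frames
#'
#' Applies the model to every frame of a trajectory (e.g. multi-model PDB
#' snapshots) and aggregates per-residue confidences: the mean over all
#' frames and a rolling mean over a window of consecutive frames.
#'
#' @param frames list of [atomic_structure()] sharing residue composition.
#' @param params a `model_params` object.
#' @param window rolling-mean window in frames (default 4).
#' @param ... passed to [predict.model_params()].
#' @return list with `frames` (per-frame [prediction_result()]s), `mean`
#'   (a [prediction_result()] of per-residue means) and `rolling` (list of
#'   per-window mean results, `length(frames) - window + 1` of them).
#' @export
predict_ensemble <- function(frames, params, window = 4L, ...) {
  if (length(frames) == 0L) stop("no frames")
  results <- lapply(frames, function(f) predict(params, f, ...))
  ref <- results[[1L]]
  key <- function(r) paste(r$chain_tag, r$author_number, r$residue_name)
  for (r in results[-1L]) {
    if (!identical(key(r), key(ref))) stop("frames differ in residue composition")
  }
  channels <- attr(ref, "channels")
  conf_of <- function(r) as.matrix(as.data.frame(r)[channels])
  stack <- lapply(results, conf_of)
  mean_over <- function(idx) {
    m <- Reduce(`+`, stack[idx]) / length(idx)
    out <- as.data.frame(ref)[c("chain_tag", "author_number", "residue_name")]
    for (ci in seq_along(channels)) out[[channels[ci]]] <- m[, ci]
    prediction_result(out, channels)
  }
  nwin <- length(frames) - window + 1L
  rolling <- if (nwin >= 1L) {
    lapply(seq_len(nwin), function(s) mean_over(s:(s + window - 1L)))
  } else {
    list()
  }
  list(frames = results, mean = mean_over(seq_along(frames)), rolling = rolling)
}

# ---- checkpoints --------------------------------------------------------

#' Save / load model parameters
#'
#' Checkpoints are a JSON container: a header with the hyperparameters and
#' flat named numeric arrays for every weight, written at full precision.
#'
#' @param params a `model_params` object.
#' @param path checkpoint file.
#' @return `path` invisibly (`save_model`); a `model_params`
#'   (`load_model`).
#' @export
save_model <- function(params, path) {
  ser <- function(p) {
    if (is.list(p)) lapply(p, ser) else list(d = dim_of(p), v = as.numeric(p))
  }
  obj <- list(
    header = list(S = params$config$S,
                  nn_schedule = params$config$nn_schedule,
                  n_key = params$config$n_key,
                  n_head_atom = params$config$n_head_atom,
                  n_head_pool = params$config$n_head_pool,
                  channels = params$config$channels,
                  vocab = params$config$vocab),
    weights = ser(params[c("embed", "blocks", "pool", "head")])
  )
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = FALSE)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  h <- obj$header
  config <- model_config(S = unlist(h$S),
                         nn_schedule = lapply(h$nn_schedule,
                                              function(x) as.integer(unlist(x))),
                         n_key = unlist(h$n_key),
                         n_head_atom = unlist(h$n_head_atom),
                         n_head_pool = unlist(h$n_head_pool),
                         channels = unlist(h$channels),
                         vocab = unlist(h$vocab))
  deser <- function(p) {
    if (is.list(p) && identical(sort(names(p)), c("d", "v"))) {
      d <- as.integer(unlist(p$d))
      v <- as.numeric(unlist(p$v))
      if (length(d) == 1L) v else array(v, d)
    } else {
      lapply(p, deser)
    }
  }
  params <- deser(obj$weights)
  params$config <- config
  class(params) <- "model_params"
  params
}
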