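# Orchestration of the six-step reconstruction procedure: template
# preparation, decoy generation, feature encoding, model training, extended-
# chain reconstruction and PDB output.

#' Pipeline configuration
#'
#' Collects every tunable of the reconstruction pipeline with its default.
#' Defaults follow the method's study conditions: 500 decoys per template
#' (1000 when exactly one template is available), a 3-13 Angstrom decoy RMSD
#' band, hidden decrease ratios 0.9/0.8/0.7, and extended-chain torsions
#' +135/-135/180 degrees.
#'
#' @param decoys_per_template Decoys per template when several templates are
#'   used (default 500).
#' @param single_template_decoys Decoys when exactly one template is used
#'   (default 1000).
#' @param rmsd_band Decoy CA RMSD band in Angstrom (default `c(3, 13)`).
#' @param ratios Hidden-layer decrease ratios (default `c(0.9, 0.8, 0.7)`).
#' @param pretrain Run layer-wise denoising pretraining before fine-tuning?
#'   (default `TRUE`; `FALSE` keeps the random initialization).
#' @param pretrain_epochs,finetune_epochs Epoch counts (defaults 100 per
#'   layer / 300).
#' @param pretrain_lr,finetune_lr Learning rates (defaults 0.05 / 0.01).
#' @param batch_size Mini-batch size (default 20).
#' @param mask_fraction Pretraining corruption probability (default 0.3).
#' @param finetune_corrupt Masking probability at fine-tune time (default 0:
#'   noise only in pretraining).
#' @param phi,psi,omega Extended-chain torsions in degrees
#'   (defaults +135, -135, 180).
#' @param clamp_output Clamp model output into `[0, 1]`? (default `FALSE`).
#' @param seed Master integer seed; all stage seeds derive from it.
#' @param geometry Backbone geometry constants ([backbone_geometry()]).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(decoys_per_template = 500,
                            single_template_decoys = 1000,
                            rmsd_band = c(3, 13),
                            ratios = c(0.9, 0.8, 0.7),
                            pretrain = TRUE,
                            pretrain_epochs = 100, finetune_epochs = 300,
                            pretrain_lr = 0.05, finetune_lr = 0.01,
                            batch_size = 20, mask_fraction = 0.3,
                            finetune_corrupt = 0,
                            phi = 135, psi = -135, omega = 180,
                            clamp_output = FALSE,
                            seed = 1,
                            geometry = backbone_geometry()) {
  cfg <- list(decoys_per_template = decoys_per_template,
              single_template_decoys = single_template_decoys,
              rmsd_band = rmsd_band, ratios = ratios, pretrain = pretrain,
              pretrain_epochs = pretrain_epochs,
              finetune_epochs = finetune_epochs,
              pretrain_lr = pretrain_lr, finetune_lr = finetune_lr,
              batch_size = batch_size, mask_fraction = mask_fraction,
              finetune_corrupt = finetune_corrupt,
              phi = phi, psi = psi, omega = omega,
              clamp_output = clamp_output, seed = as.integer(seed),
              geometry = geometry)
  if (cfg$decoys_per_template < 1 || cfg$single_template_decoys < 1)
    stop("decoys per template must be >= 1")
  if (any(cfg$ratios <= 0 | cfg$ratios >= 1)) stop("ratios must lie in (0, 1)")
  if (!(cfg$rmsd_band[1] > 0 && cfg$rmsd_band[2] > cfg$rmsd_band[1]))
    stop("rmsd_band must satisfy 0 < low < high")
  structure(cfg, class = "pipeline_config")
}

#' Read a pipeline configuration from a flat YAML file
#' @param path YAML file whose keys are [pipeline_config()] arguments.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  bad <- setdiff(names(vals), known)
  if (length(bad)) stop("unknown config keys: ", paste(bad, collapse = ", "))
  do.call(pipeline_config, vals)
}

#' Assemble the training set from templates
#'
#' For each template (already mapped to target length via
#' [pad_or_trim_template()], or used as-is when no alignment is given):
#' generates the configured number of RMSD-banded decoys, superposes every
#' template native and every decoy onto the first template native so all
#' conformations share one coordinate system, fits one global normalization
#' scale over all structures, and encodes decoys (rows of `inputs`) and their
#' template natives (matching rows of `labels`) as feature vectors.
#'
#' @param templates A list; each element either a [backbone_structure()] or a
#'   list with fields `structure` and optional `alignment` (see
#'   [pad_or_trim_template()]).
#' @param config A [pipeline_config()].
#' @param target_sequence Optional target sequence for alignment mapping.
#' @return List: `inputs`, `labels` (matrices, one decoy per row), `scale`,
#'   `include` (coordinate channel indices entering the loss),
#'   `mask_residues` (logical, non-vacant in every template), `reference`
#'   (first template native after padding), `centroid` (training-set mean
#'   coordinate, Angstrom), `decoy_sets`.
#' @export
prepare_training_set <- function(templates, config = pipeline_config(),
                                 target_sequence = NULL) {
  if (length(templates) == 0) stop_stage("prepare", "no templates supplied")
  natives <- lapply(seq_along(templates), function(t) {
    tt <- templates[[t]]
    s <- if (inherits(tt, "backbone_structure")) tt else tt$structure
    aln <- if (inherits(tt, "backbone_structure")) NULL else tt$alignment
    if (!is.null(aln)) s <- pad_or_trim_template(s, aln, target_sequence)
    validate_backbone(s)
    s
  })
  L <- n_residues(natives[[1]])
  if (!all(vapply(natives, n_residues, integer(1)) == L))
    stop_stage("prepare", "templates map to differing target lengths")

  n_per <- if (length(natives) == 1) config$single_template_decoys
           else config$decoys_per_template
  decoy_sets <- lapply(seq_along(natives), function(t) {
    plog("prepare", "template %d/%d: generating %d decoys in [%g, %g] A",
         t, length(natives), n_per, config$rmsd_band[1], config$rmsd_band[2])
    generate_decoys(natives[[t]], n_per, config$rmsd_band,
                    seed = derive_seed(config$seed, 100 + t))
  })

  # common frame: superpose everything onto the first template native
  ref <- natives[[1]]
  mask_res <- Reduce(`&`, lapply(natives, function(s) !s$vacant))
  for (t in seq_along(natives)) {
    if (t > 1) {
      sp <- kabsch_superpose(ca_xyz(natives[[t]]), ca_xyz(ref), mask = mask_res)
      natives[[t]] <- apply_superposition(sp, natives[[t]])
    }
    decoy_sets[[t]]$decoys <- lapply(decoy_sets[[t]]$decoys, function(d) {
      sp <- kabsch_superpose(ca_xyz(d), ca_xyz(natives[[t]]), mask = mask_res)
      apply_superposition(sp, d)
    })
  }

  scale <- fit_scale(c(natives, unlist(lapply(decoy_sets, `[[`, "decoys"),
                       recursive = FALSE)))
  label_rows <- lapply(natives, structure_to_features, scale = scale)
  inputs <- do.call(rbind, unlist(lapply(seq_along(decoy_sets), function(t)
    lapply(decoy_sets[[t]]$decoys, structure_to_features, scale = scale)),
    recursive = FALSE))
  labels <- do.call(rbind, rep(label_rows,
                               vapply(decoy_sets, function(d) length(d$decoys),
                                      integer(1))))
  include <- coord_channel_idx(which(mask_res))
  centroid <- colMeans(do.call(rbind, lapply(natives, function(s)
    backbone_xyz(s)[rep(mask_res, each = 4), , drop = FALSE])))
  list(inputs = inputs, labels = labels, scale = scale, include = include,
       mask_residues = mask_res, reference = ref, centroid = centroid,
       decoy_sets = decoy_sets)
}

#' Train the reconstruction model
#'
#' Builds the stacked autoencoder with widths from the decrease-ratio rule,
#' optionally runs layer-wise denoising pretraining, fine-tunes end-to-end
#' under the coordinate-RMSD objective, and freezes the normalization scale
#' (plus reference frame and centroid) into the model.
#'
#' @param training A list from [prepare_training_set()] (or one with the same
#'   fields).
#' @param config A [pipeline_config()].
#' @return A trained `sda_model` carrying `scale`, `reference`, `centroid`
#'   and `include`.
#' @export
train_model <- function(training, config = pipeline_config()) {
  input_dim <- ncol(training$inputs)
  model <- new_sda_model(input_dim, ratios = config$ratios,
                         seed = derive_seed(config$seed, 200))
  if (config$pretrain && config$pretrain_epochs > 0) {
    plog("train", "layer-wise pretraining: %d epochs/layer", config$pretrain_epochs)
    model <- pretrain_layerwise(model, training$inputs,
                                epochs = config$pretrain_epochs,
                                learning_rate = config$pretrain_lr,
                                mask_fraction = config$mask_fraction,
                                seed = derive_seed(config$seed, 201),
                                batch_size = config$batch_size)
  }
  plog("train", "fine-tuning: %d epochs", config$finetune_epochs)
  model <- finetune(model, training$inputs, training$labels,
                    epochs = config$finetune_epochs,
                    learning_rate = config$finetune_lr,
                    batch_size = config$batch_size,
                    seed = derive_seed(config$seed, 202),
                    include = training$include,
                    corrupt_fraction = config$finetune_corrupt)
  model$scale <- training$scale
  model$reference <- training$reference
  model$centroid <- training$centroid
  model$include <- training$include
  model$mask_residues <- training$mask_residues
  model
}

#' Reconstruct the target backbone with a trained model
#'
#' Builds the extended chain at the configured torsions (or takes a supplied
#' crude input conformation), places it in the training frame -- the extended
#' chain by translating its centroid onto the training-set centroid, an
#' arbitrary structure by CA superposition onto the stored reference --
#' normalizes under the model's frozen scale (values outside the training box
#' are clipped into `[0, 1]` with a message), runs the forward pass and
#' denormalizes the output.
#'
#' @param model A trained `sda_model` (from [train_model()]).
#' @param sequence Target sequence; `13 * L` must equal the model input
#'   width.
#' @param config A [pipeline_config()] (torsions, clamp flag).
#' @param input_structure Optional [backbone_structure()] to use as the crude
#'   input instead of the extended chain.
#' @param write_to Optional path; if given the result is written as PDB.
#' @return The reconstructed [backbone_structure()].
#' @export
reconstruct <- function(model, sequence, config = pipeline_config(),
                        input_structure = NULL, write_to = NULL) {
  sequence <- split_sequence(sequence)
  L <- length(sequence)
  if (13 * L != model$input_dim)
    stop_stage("reconstruct",
               "sequence length %d does not match the trained input width %d (L = %d)",
               L, model$input_dim, model$input_dim %/% 13)
  if (is.null(model$scale)) stop_stage("reconstruct", "model has no frozen scale; train it first")
  if (is.null(input_structure)) {
    crude <- build_extended_chain(sequence, phi = config$phi, psi = config$psi,
                                  omega = config$omega,
                                  constants = config$geometry)
    pts <- backbone_xyz(crude)
    pts <- sweep(pts, 2, colMeans(pts))                 # centre
    pts <- sweep(pts, 2, model$centroid, `+`)
    crude <- set_backbone_xyz(crude, pts)
  } else {
    validate_backbone(input_structure)
    if (n_residues(input_structure) != L)
      stop_stage("reconstruct", "input structure length differs from target length")
    sp <- kabsch_superpose(ca_xyz(input_structure), ca_xyz(model$reference),
                           mask = model$mask_residues)
    crude <- apply_superposition(sp, input_structure)
  }
  feats <- structure_to_features(crude, model$scale)
  out_of_box <- sum(feats < 0 | feats > 1)
  if (out_of_box > 0) {
    plog("reconstruct", "clipping %d feature values outside the training box", out_of_box)
    feats <- pmin(pmax(feats, 0), 1)
  }
  feats[residue_channel_idx(L)] <- encode_residue_types(sequence)
  out <- sda_forward(model, feats, clamp01 = config$clamp_output)
  res <- features_to_structure(out, model$scale, sequence, id = "reconstructed")
  if (!is.null(write_to)) write_pdb(res, write_to)
  res
}

#' Run the whole reconstruction pipeline
#'
#' Executes template preparation, decoy generation, training, reconstruction
#' and evaluation in order, writing every artifact under `out_dir`: the model
#' checkpoint, the decoy manifest, the reconstructed PDB and a JSON
#' evaluation summary.  Fully seeded: rerunning with the same configuration
#' reproduces the output PDB byte for byte.
#'
#' @param templates As in [prepare_training_set()].
#' @param target_sequence Target sequence (string, vector or FASTA path).
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created if needed).
#' @param native Optional true native structure; when given, the evaluation
#'   summary reports the reconstruction's quality against it.
#' @return A report list: `model_path`, `manifest_path`, `pdb_path`,
#'   `evaluation_path`, `evaluation` (tibble or `NULL`), `model`,
#'   `reconstruction`.
#' @export
run_pipeline <- function(templates, target_sequence, config = pipeline_config(),
                         out_dir = tempfile("prsda_run_"), native = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  target_sequence <- read_sequence(target_sequence)

  training <- tryCatch(
    prepare_training_set(templates, config, target_sequence),
    error = function(e) stop_stage("prepare", "%s", conditionMessage(e)))

  manifest_path <- file.path(out_dir, "decoys")
  # manifest only (decoy PDBs are reproducible from the seed); full sets via
  # write_decoy_set()
  dir.create(manifest_path, showWarnings = FALSE)
  manifest <- do.call(rbind, lapply(training$decoy_sets, function(ds)
    data.frame(template_id = ds$template_id,
               decoy_id = vapply(ds$decoys, function(d) d$id, character(1)),
               rmsd_to_native = sprintf("%.6f", ds$rmsd_to_native),
               seed = ds$seed)))
  manifest_file <- file.path(manifest_path, "manifest.tsv")
  utils::write.table(manifest, manifest_file, sep = "\t", quote = FALSE,
                     row.names = FALSE)

  model <- tryCatch(train_model(training, config),
                    error = function(e) stop_stage("train", "%s", conditionMessage(e)))
  model_path <- file.path(out_dir, "model.rds")
  save_sda(model, model_path)

  pdb_path <- file.path(out_dir, "reconstructed.pdb")
  recon <- tryCatch(
    reconstruct(model, target_sequence, config, write_to = pdb_path),
    error = function(e) stop_stage("reconstruct", "%s", conditionMessage(e)))

  evaluation <- NULL
  eval_path <- file.path(out_dir, "evaluation.json")
  ref <- native %||% training$reference
  evaluation <- evaluate_model(recon, ref)
  jsonlite::write_json(as.list(evaluation), eval_path,
                       auto_unbox = TRUE, digits = NA)
  plog("report", "CA RMSD to %s: %.3f A; GDT-TS %.3f",
       if (is.null(native)) "reference template" else "native",
       evaluation$ca_rmsd, evaluation$gdt_ts)

  list(model_path = model_path, manifest_path = manifest_file,
       pdb_path = pdb_path, evaluation_path = eval_path,
       evaluation = evaluation, model = model, reconstruction = recon)
}
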