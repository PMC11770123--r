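# Pipeline orchestration: one configuration object drives
# simulate -> pretrain-ae -> train-align -> train-diffusion -> generate ->
# evaluate, with per-stage seeds fanned out from one global seed, stage
# artifacts under a single run directory, and a line-oriented JSON log.

#' Build a run configuration
#'
#' Defaults follow the full-scale training setup (AdamW, learning rate 1e-5,
#' weight decay 1e-5, effective batch 64 by gradient accumulation, alignment
#' early-stop threshold 300 epochs, diffusion 1000 epochs with checkpoints
#' every 25, 1000 diffusion steps); the data/model geometry defaults are
#' desk-scale so a pipeline run finishes on a laptop CPU.
#'
#' @param seed global RNG seed; per-stage seeds derive from it by fixed
#'   offsets.
#' @param out_dir run directory.
#' @param n_per_class,split_fractions,bands,canvas_um,noise_sd,n_texture_elements
#'   synthetic dataset settings (see [phantom_spec()]).
#' @param width,n_down,patch,K alignment model geometry.
#' @param lr,weight_decay,accum optimizer settings shared by all stages.
#' @param ae_steps autoencoder pretraining updates.
#' @param align_epochs,align_patience alignment training bounds.
#' @param diff_epochs,ckpt_every,T_steps,sample_steps diffusion settings.
#' @param unet_base,unet_mult UNet width settings.
#' @return a `run_config` list (round-trips through YAML unchanged).
#' @export
run_config <- function(seed = 1L, out_dir = tempfile("ramanstain_run"),
                       n_per_class = 5L, split_fractions = c(0.6, 0.2, 0.2),
                       bands = 16L, canvas_um = c(16, 16), noise_sd = 0.02,
                       n_texture_elements = 4L,
                       width = 8L, n_down = 2L, patch = 4L, K = 4L,
                       lr = 1e-5, weight_decay = 1e-5, accum = 64L,
                       ae_steps = 50L, align_epochs = 300L,
                       align_patience = 300L,
                       diff_epochs = 1000L, ckpt_every = 25L,
                       T_steps = 1000L, sample_steps = 25L,
                       unet_base = 8L, unet_mult = c(1, 2)) {
  cfg <- list(seed = as.integer(seed), out_dir = out_dir,
              n_per_class = as.integer(n_per_class),
              split_fractions = split_fractions, bands = as.integer(bands),
              canvas_um = canvas_um, noise_sd = noise_sd,
              n_texture_elements = as.integer(n_texture_elements),
              width = as.integer(width), n_down = as.integer(n_down),
              patch = as.integer(patch), K = as.integer(K),
              lr = lr, weight_decay = weight_decay, accum = as.integer(accum),
              ae_steps = as.integer(ae_steps),
              align_epochs = as.integer(align_epochs),
              align_patience = as.integer(align_patience),
              diff_epochs = as.integer(diff_epochs),
              ckpt_every = as.integer(ckpt_every),
              T_steps = as.integer(T_steps),
              sample_steps = as.integer(sample_steps),
              unet_base = as.integer(unet_base), unet_mult = unet_mult)
  class(cfg) <- "run_config"
  cfg
}

#' Serialize / restore a run configuration
#' @param config a [run_config()].
#' @param path YAML file path.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  ints <- c("seed", "n_per_class", "bands", "n_texture_elements", "width",
            "n_down", "patch", "K", "accum", "ae_steps", "align_epochs",
            "align_patience", "diff_epochs", "ckpt_every", "T_steps",
            "sample_steps", "unet_base")
  for (nm in ints) cfg[[nm]] <- as.integer(cfg[[nm]])
  class(cfg) <- "run_config"
  cfg
}

log_line <- function(path, stage, ...) {
  rec <- c(list(stage = stage, time = format(Sys.time(), "%Y-%m-%dT%H:%M:%S")),
           list(...))
  cat(jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA), "\n",
      file = path, append = TRUE, sep = "")
}

# Load manifest records into training items for the alignment model.
manifest_to_items <- function(manifest, classes = PHANTOM_CLASSES) {
  recs <- manifest$records
  items <- list(train = list(), val = list(), test = list())
  for (i in seq_len(nrow(recs))) {
    lab <- match(recs$class_label[i], classes)
    rgb <- read_rgb_image(recs$rgb_path[i])
    cube <- read_cube(recs$cube_path[i])
    sp <- recs$split[i]
    items[[sp]] <- c(items[[sp]], list(
      list(x = rgb, modality = "HE", label = lab, sample_id = recs$sample_id[i]),
      list(x = cube, modality = "RA", label = lab, sample_id = recs$sample_id[i])))
  }
  items
}

#' Run the full pipeline
#'
#' Executes every stage under `config$out_dir`, logging stage shapes and
#' metrics to `log.jsonl` and writing a final `report.json`. Any stage
#' failure halts the run with the stage name; artifacts written by earlier
#' stages are left in place.
#'
#' @param config a [run_config()].
#' @param dry_run if `TRUE`, print the resolved stage plan and write
#'   nothing.
#' @return the report list (or the plan, for a dry run), invisibly.
#' @export
run_pipeline <- function(config, dry_run = FALSE) {
  stopifnot(inherits(config, "run_config"))
  plan <- c("simulate: generate synthetic co-registered dataset",
            "pretrain-ae: autoencoder pretraining of the H&E encoder",
            "train-align: cross-modal alignment network",
            "train-diffusion: conditional UNet",
            "generate: H&E synthesis from test Raman cubes",
            "evaluate: region-majority diagnosis of generated images")
  if (dry_run) {
    cat(sprintf("run_pipeline plan (seed %d, out %s):\n", config$seed,
                config$out_dir))
    cat(paste0("  ", seq_along(plan), ". ", plan, collapse = "\n"), "\n")
    return(invisible(plan))
  }
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(config$out_dir, "log.jsonl")
  write_run_config(config, file.path(config$out_dir, "config.yaml"))
  run_stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  manifest <- run_stage("simulate", {
    m <- generate_dataset(config$n_per_class, config$split_fractions,
                          out_dir = file.path(config$out_dir, "dataset"),
                          rng_seed = stage_seed(config$seed, "simulate"),
                          bands = config$bands, canvas_um = config$canvas_um,
                          noise_sd = config$noise_sd,
                          n_texture_elements = config$n_texture_elements)
    log_line(log_path, "simulate", n_records = nrow(m$records))
    m
  })
  items <- manifest_to_items(manifest)

  ae <- run_stage("pretrain-ae", {
    he_train <- Filter(function(it) it$modality == "HE", items$train)
    if (!length(he_train)) stop("no H&E training images")
    a <- build_autoencoder(3L, width = config$width, n_down = config$n_down,
                           seed = stage_seed(config$seed, "autoencoder"))
    a <- pretrain_autoencoder(a, lapply(he_train, `[[`, "x"),
                              steps = config$ae_steps, lr = config$lr,
                              weight_decay = config$weight_decay,
                              seed = stage_seed(config$seed, "autoencoder"))
    log_line(log_path, "pretrain-ae", steps = config$ae_steps,
             final_mse = a$loss_history[length(a$loss_history)],
             input_shape = dim(he_train[[1]]$x),
             latent_shape = encoder_output_shape(dim(he_train[[1]]$x),
                                                 config$n_down, config$width))
    a
  })

  aln <- run_stage("train-align", {
    acfg <- alignnet_config(bands = config$bands, width = config$width,
                            n_down = config$n_down, patch = config$patch,
                            K = config$K, lr = config$lr,
                            weight_decay = config$weight_decay,
                            accum = config$accum,
                            epochs = config$align_epochs,
                            patience = config$align_patience)
    m <- build_alignnet(freeze_encoder(ae), acfg,
                        seed = stage_seed(config$seed, "alignnet"))
    m <- train_alignnet(m, list(train = items$train, val = items$val),
                        seed = stage_seed(config$seed, "alignnet"))
    save_checkpoint(m, file.path(config$out_dir, "alignnet.rds"))
    utils::write.csv(m$metrics, file.path(config$out_dir, "align_metrics.csv"),
                     row.names = FALSE)
    last <- m$metrics[m$metrics$split == "val", ]
    log_line(log_path, "train-align", epochs = max(m$metrics$epoch),
             updates = m$updates,
             val_accuracy = if (nrow(last)) last$accuracy[nrow(last)] else NA)
    m
  })

  schedule <- noise_schedule(config$T_steps)
  unet <- run_stage("train-diffusion", {
    he_train <- Filter(function(it) it$modality == "HE", items$train)
    tiles <- lapply(he_train, function(it) it$x * 2 - 1)
    labels <- vapply(he_train, `[[`, 0L, "label")
    ucfg <- unet_config(dim(tiles[[1]])[2], in_ch = 3L,
                        base = config$unet_base, mult = config$unet_mult,
                        d_ctx = aln$config$d_proj)
    u <- build_unet(ucfg, seed = stage_seed(config$seed, "diffusion"))
    u <- train_diffusion(u, tiles, labels, generate_targets(aln, "HE"),
                         schedule, epochs = config$diff_epochs,
                         lr = config$lr, weight_decay = config$weight_decay,
                         ckpt_every = config$ckpt_every,
                         ckpt_dir = file.path(config$out_dir, "checkpoints"),
                         seed = stage_seed(config$seed, "diffusion"))
    save_checkpoint(u, file.path(config$out_dir, "unet.rds"))
    log_line(log_path, "train-diffusion", epochs = config$diff_epochs,
             final_loss = u$loss_history[length(u$loss_history)])
    u
  })

  gen <- run_stage("generate", {
    test_ra <- Filter(function(it) it$modality == "RA", items$test)
    out <- list()
    gen_dir <- file.path(config$out_dir, "generated")
    dir.create(gen_dir, showWarnings = FALSE)
    for (j in seq_along(test_ra)) {
      img <- generate_from_raman(test_ra[[j]]$x, aln, unet, schedule,
                                 steps = config$sample_steps,
                                 seed = stage_seed(config$seed, "sampling") + j)
      write_rgb_image((img + 1) / 2,
                      file.path(gen_dir, paste0(test_ra[[j]]$sample_id, "_gen.png")))
      out[[j]] <- list(sample_id = test_ra[[j]]$sample_id,
                       label = test_ra[[j]]$label, image = img)
    }
    log_line(log_path, "generate", n_images = length(out))
    out
  })

  report <- run_stage("evaluate", {
    calls <- vapply(gen, function(g)
      predict_alignnet(aln, (g$image + 1) / 2, "HE")$class, "")
    truths <- vapply(gen, function(g) aln$config$classes[g$label], "")
    n <- length(calls)
    diag <- if (n > 0)
      vapply(seq_len(n), function(i)
        diagnose_sample(calls[i], truths[i], n_regions = 1L, threshold = 0L),
        "") else character(0)
    acc <- if (n > 0) cohort_accuracy(diag) else list(fraction = NA, percent = NA)
    rep <- list(n_generated = n, calls = as.list(calls),
                truths = as.list(truths),
                generated_diagnostic_accuracy = acc$percent,
                align_updates = aln$updates,
                diffusion_final_loss = unet$loss_history[length(unet$loss_history)])
    jsonlite::write_json(rep, file.path(config$out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA)
    log_line(log_path, "evaluate", accuracy = acc$percent)
    rep
  })
  invisible(report)
}
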