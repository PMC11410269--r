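# ---- orchestration ----------------------------------------------------------
# The training schedule has three stages: pretrain the homography network on a
# synthetic-warp corpus, fine-tune it on the target dataset, then train the
# reconstruction networks with the homography frozen. run_stage() executes one
# stage with a manifest; demo_end_to_end() is the self-contained desk-scale
# smoke pipeline.

#' Run configuration
#'
#' Bundles seeds, stage schedules and network/loss settings. Defaults follow
#' the published schedule: 150 pretraining epochs, 50 fine-tuning epochs,
#' 20 reconstruction epochs, Adam with initial learning rate 1e-4.
#' @param seed master seed; all stage randomness derives from it.
#' @param epochs named vector of stage epochs.
#' @param lr Adam learning rate.
#' @param hcfg,rcfg,lw network configs and loss weights.
#' @param ccfg distortion-correction config.
#' @param work_dir where stage artifacts (weights, logs, manifests) go.
#' @return list of class `"run_config"`.
#' @export
run_config <- function(seed = 1L,
                       epochs = c(pretrain = 150L, finetune = 50L, reconstruction = 20L),
                       lr = 1e-4, hcfg = homography_config(), rcfg = recon_config(),
                       lw = loss_weights(), ccfg = correction_config(),
                       work_dir = file.path(tempdir(), "endostitch_run")) {
  structure(list(seed = as.integer(seed), epochs = epochs, lr = lr, hcfg = hcfg,
                 rcfg = rcfg, lw = lw, ccfg = ccfg, work_dir = work_dir),
            class = "run_config")
}

config_hash <- function(cfg) {
  f <- tempfile()
  on.exit(unlink(f))
  dput(cfg[setdiff(names(cfg), "work_dir")], file = f, control = c("keepNA", "keepInteger"))
  unname(tools::md5sum(f))
}

log_line <- function(path, ...) {
  msg <- paste0(format(Sys.time(), "%H:%M:%S "), ...)
  message(msg)
  cat(msg, "\n", file = path, append = TRUE)
  invisible(NULL)
}

#' Execute one pipeline stage
#'
#' Stages: `"gen_data"` (synthesize the training/test quadruples),
#' `"pretrain"` (homography network on a fresh synthetic-warp corpus),
#' `"finetune"` (homography network on the target dataset), and
#' `"reconstruction"` (reconstruction networks with the homography frozen).
#' Each stage writes its weights plus a manifest with the resolved
#' configuration, its hash and the seed; a later stage refuses to run when
#' its prerequisite artifact is missing and names the producing stage.
#' @param stage stage name.
#' @param cfg a `"run_config"`.
#' @param n_train,n_test dataset sizes for `"gen_data"`.
#' @param size,patch source/patch sizes for `"gen_data"`.
#' @return invisibly, the stage's main artifact path.
#' @export
run_stage <- function(stage = c("gen_data", "pretrain", "finetune", "reconstruction"),
                      cfg = run_config(), n_train = 64L, n_test = 16L,
                      size = c(256L, 256L), patch = c(128L, 128L)) {
  stage <- match.arg(stage)
  dir.create(cfg$work_dir, recursive = TRUE, showWarnings = FALSE)
  logf <- file.path(cfg$work_dir, "run.log")
  need <- function(path, producer) {
    if (!file.exists(path))
      stop("stage '", stage, "' needs ", basename(path),
           "; run stage '", producer, "' first", call. = FALSE)
    path
  }
  paths <- list(train = file.path(cfg$work_dir, "train"),
                test = file.path(cfg$work_dir, "test"),
                hweights = file.path(cfg$work_dir, "homography.rds"),
                rweights = file.path(cfg$work_dir, "reconstruction.rds"))
  log_line(logf, "stage ", stage, ": seed=", cfg$seed,
           " lr=", cfg$lr, " epochs=", paste(names(cfg$epochs), cfg$epochs,
                                             sep = "=", collapse = ","),
           " config_hash=", config_hash(cfg))
  out <- switch(stage,
    gen_data = {
      generate_dataset(n_train, dir = paths$train, seed = cfg$seed,
                       size = size, patch = patch)
      generate_dataset(n_test, dir = paths$test, seed = cfg$seed + 1L,
                       size = size, patch = patch)
      log_line(logf, "wrote ", n_train, " train / ", n_test, " test samples")
      paths$train
    },
    pretrain = {
      corpus <- generate_dataset(n_train, seed = cfg$seed + 2L, size = size,
                                 patch = patch)
      w <- train_homography(corpus, cfg = cfg$hcfg,
                            epochs = cfg$epochs[["pretrain"]], lr = cfg$lr,
                            seed = cfg$seed)
      saveRDS(w_to_list(w), paths$hweights)
      log_line(logf, "pretrained homography for ", cfg$epochs[["pretrain"]],
               " epochs; final loss ", format(utils::tail(attr(w, "loss_log"), 1), digits = 5))
      paths$hweights
    },
    finetune = {
      need(file.path(paths$train, "index.txt"), "gen_data")
      w <- w_from_list(readRDS(need(paths$hweights, "pretrain")))
      w <- train_homography(paths$train, weights = w,
                            epochs = cfg$epochs[["finetune"]], lr = cfg$lr,
                            seed = cfg$seed + 3L)
      saveRDS(w_to_list(w), paths$hweights)
      log_line(logf, "fine-tuned homography for ", cfg$epochs[["finetune"]], " epochs")
      paths$hweights
    },
    reconstruction = {
      need(file.path(paths$train, "index.txt"), "gen_data")
      hw <- w_from_list(readRDS(need(paths$hweights, "finetune")))
      w <- train_reconstruction(paths$train, hw, cfg = cfg$rcfg, lw = cfg$lw,
                                epochs = cfg$epochs[["reconstruction"]],
                                lr = cfg$lr, seed = cfg$seed + 4L)
      saveRDS(w_to_list(w), paths$rweights)
      log_line(logf, "trained reconstruction for ",
               cfg$epochs[["reconstruction"]], " epochs")
      paths$rweights
    })
  manifest <- list(stage = stage, seed = cfg$seed, config_hash = config_hash(cfg),
                   epochs = as.list(cfg$epochs), lr = cfg$lr,
                   artifact = basename(out))
  yaml::write_yaml(manifest, file.path(cfg$work_dir, paste0("manifest_", stage, ".yaml")))
  invisible(out)
}

# parameter stores are environments; serialize as plain lists
w_to_list <- function(st) {
  list(w = st$w, cfg = attr(st, "cfg"), loss_log = attr(st, "loss_log"))
}

w_from_list <- function(x) {
  st <- param_store(x$w)
  attr(st, "cfg") <- x$cfg
  attr(st, "loss_log") <- x$loss_log
  st
}

#' Self-contained end-to-end demonstration
#'
#' Generates a small synthetic dataset (64 train / 16 test quadruples of
#' 128 x 128 patches), runs the three-stage schedule at reduced epochs
#' (2 pretraining, 1 fine-tuning, 2 reconstruction) with reduced network
#' widths, stitches the held-out set with both the trained and an untrained
#' model, and reports the metric battery for each. The full-width
#' architectures are unchanged in structure; only widths and the low-res
#' working resolution are scaled to desk size.
#' @param seed integer seed.
#' @param work_dir artifact directory.
#' @param n_train,n_test dataset sizes.
#' @param verbose print stage progress.
#' @return list with `trained`, `untrained` (each a [batch_report()] result),
#'   `errors` (total stitching failures) and the stage artifact paths.
#' @export
demo_end_to_end <- function(seed = 1L, work_dir = file.path(tempdir(), "endostitch_demo"),
                            n_train = 64L, n_test = 16L, verbose = FALSE) {
  hcfg <- homography_config(levels = 2L, channels = c(8L, 16L),
                            corr_radius = c(4L, 2L), head_channels = c(24L, 16L),
                            max_offset = 24)
  rcfg <- recon_config(base = 8L, highres_channels = 6L, lowres_size = 64L,
                       perceptual_channels = c(8L, 16L, 24L))
  cfg <- run_config(seed = seed,
                    epochs = c(pretrain = 2L, finetune = 1L, reconstruction = 2L),
                    lr = 1e-3, hcfg = hcfg, rcfg = rcfg, work_dir = work_dir)
  withCallingHandlers({
    run_stage("gen_data", cfg, n_train = n_train, n_test = n_test,
              size = c(256L, 256L), patch = c(128L, 128L))
    run_stage("pretrain", cfg, n_train = n_train)
    run_stage("finetune", cfg)
    run_stage("reconstruction", cfg)
  }, message = function(m) if (!verbose) invokeRestart("muffleMessage"))
  test <- read_dataset(file.path(work_dir, "test"))
  hw <- w_from_list(readRDS(file.path(work_dir, "homography.rds")))
  rw <- w_from_list(readRDS(file.path(work_dir, "reconstruction.rds")))
  hw0 <- init_homography_weights(hcfg, seed + 10L)
  rw0 <- init_recon_weights(rcfg, seed + 11L)
  trained <- batch_report(test, hw, rw, mode = "resize")
  untrained <- batch_report(test, hw0, rw0, mode = "resize")
  list(trained = trained, untrained = untrained,
       errors = trained$errors,
       artifacts = work_dir)
}
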