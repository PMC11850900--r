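#' Read a diffusion-weighted volume with its gradient table
#'
#' Reads a 4D NIfTI plus FSL-style plain-text gradient files: `bval` is one
#' whitespace-separated row of b-values, `bvec` three rows holding the x, y,
#' z components. Volume counts must agree and diffusion-weighted directions
#' must be unit norm within 1e-3.
#'
#' @param nifti Path to the 4D NIfTI file.
#' @param bval,bvec Paths to the gradient table files.
#' @return A `dwi_volume`.
#' @export
read_dwi <- function(nifti, bval, bvec) {
  img <- RNifti::readNifti(nifti)
  data <- array(as.numeric(img), dim(img))
  if (length(dim(data)) != 4) stop("expected a 4D NIfTI", call. = FALSE)
  bvals <- scan(bval, quiet = TRUE)
  bv <- as.matrix(utils::read.table(bvec))
  if (nrow(bv) != 3)
    stop("bvec file must have exactly 3 rows", call. = FALSE)
  if (ncol(bv) != length(bvals) || length(bvals) != dim(data)[4])
    stop("volume count mismatch between NIfTI, bval and bvec", call. = FALSE)
  scheme <- gradient_scheme(bvals, t(bv))
  vs <- RNifti::pixdim(img)[1]
  structure(list(data = data, scheme = scheme, voxel_size = vs),
            class = "dwi_volume")
}

#' Write a diffusion-weighted volume with its gradient table
#'
#' @param dwi A `dwi_volume`.
#' @param nifti,bval,bvec Output paths.
#' @return Invisibly, the NIfTI path.
#' @export
write_dwi <- function(dwi, nifti, bval, bvec) {
  stopifnot(inherits(dwi, "dwi_volume"))
  img <- RNifti::asNifti(dwi$data)
  RNifti::pixdim(img) <- c(rep(dwi$voxel_size, 3), 1)
  RNifti::writeNifti(img, nifti)
  writeLines(paste(format(dwi$scheme$bvals, trim = TRUE), collapse = " "),
             bval)
  write.table(t(dwi$scheme$bvecs), bvec, row.names = FALSE,
              col.names = FALSE)
  invisible(nifti)
}

#' Read / write SH coefficient volumes with a metadata sidecar
#'
#' SH volumes are stored as 4D NIfTI with the coefficient index on the 4th
#' axis and a YAML sidecar recording `lmax`, the basis convention, the
#' normalized flag and the index order.
#'
#' @param sh 4D SH array.
#' @param path Output NIfTI path; the sidecar is `path` with a `.yaml`
#'   extension appended.
#' @param lmax Even SH order.
#' @param normalized Whether the constant coefficient has been divided out.
#' @param voxel_size Isotropic voxel edge in mm.
#' @return `write_sh_volume()` invisibly returns `path`; `read_sh_volume()`
#'   a list with `sh`, `lmax`, `normalized`, `voxel_size`.
#' @export
write_sh_volume <- function(sh, path, lmax = 8, normalized = FALSE,
                            voxel_size = 1.25) {
  stopifnot(length(dim(sh)) == 4)
  img <- RNifti::asNifti(sh)
  RNifti::pixdim(img) <- c(rep(voxel_size, 3), 1)
  RNifti::writeNifti(img, path)
  yaml::write_yaml(list(lmax = lmax, basis = "real_symmetric",
                        normalized = normalized,
                        index_order = "l ascending, m ascending",
                        voxel_size = voxel_size),
                   paste0(path, ".yaml"))
  invisible(path)
}

#' @rdname write_sh_volume
#' @export
read_sh_volume <- function(path) {
  img <- RNifti::readNifti(path)
  meta <- yaml::read_yaml(paste0(path, ".yaml"))
  list(sh = array(as.numeric(img), dim(img)), lmax = meta$lmax,
       normalized = meta$normalized, voxel_size = meta$voxel_size)
}

#' Write / read a peak volume as NIfTI pairs
#'
#' Peak directions are stored as a 4D NIfTI with `5 * 3` channels (x, y, z
#' components of up to 5 peaks, zero-padded), amplitudes as a 5-channel
#' NIfTI.
#'
#' @param peaks A `peak_volume`.
#' @param dir_path,amp_path Output NIfTI paths.
#' @return Invisibly, `dir_path`.
#' @export
write_peaks <- function(peaks, dir_path, amp_path) {
  stopifnot(inherits(peaks, "peak_volume"))
  d <- dim(peaks$counts)
  RNifti::writeNifti(RNifti::asNifti(array(peaks$directions,
                                           c(d, 15L))), dir_path)
  RNifti::writeNifti(RNifti::asNifti(peaks$amplitudes), amp_path)
  invisible(dir_path)
}

#' @rdname write_peaks
#' @export
read_peaks <- function(dir_path, amp_path) {
  dirs <- RNifti::readNifti(dir_path)
  amps <- RNifti::readNifti(amp_path)
  d <- dim(amps)[1:3]
  amp <- array(as.numeric(amps), dim(amps))
  structure(list(directions = array(as.numeric(dirs), c(d, 5L, 3L)),
                 amplitudes = amp,
                 counts = array(rowSums(matrix(amp, prod(d), 5) > 0), d),
                 max_peaks = 5L),
            class = "peak_volume")
}

#' Save / load a trained DSR model as structured text
#'
#' The model directory holds the architecture and training configuration
#' (YAML), the loss history (CSV) and all weights (one CSV per tensor) —
#' plain text only.
#'
#' @param model A `dsr_model`.
#' @param dir Model directory.
#' @return `save_dsr_model()` invisibly returns `dir`; `load_dsr_model()` the
#'   restored `dsr_model`.
#' @export
save_dsr_model <- function(model, dir) {
  stopifnot(inherits(model, "dsr_model"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  yaml::write_yaml(list(spec = unclass(model$spec),
                        config = unclass(model$config)),
                   file.path(dir, "model.yaml"))
  utils::write.csv(model$history, file.path(dir, "history.csv"),
                   row.names = FALSE)
  wm <- function(x, name) utils::write.table(
    x, file.path(dir, paste0(name, ".csv")), row.names = FALSE,
    col.names = FALSE, sep = ",")
  for (i in seq_along(model$params$layers)) {
    L <- model$params$layers[[i]]
    wm(L$W, sprintf("layer%d_W", i))
    wm(rbind(L$b, L$gamma, L$beta, L$run_mean, L$run_var),
       sprintf("layer%d_vec", i))
  }
  wm(model$params$out$W, "out_W")
  wm(matrix(model$params$out$b, 1), "out_b")
  invisible(dir)
}

#' @rdname save_dsr_model
#' @export
load_dsr_model <- function(dir) {
  meta <- yaml::read_yaml(file.path(dir, "model.yaml"))
  spec <- do.call(dsr_model_spec, meta$spec[c("input_dim", "hidden",
                                              "output_dim")])
  config <- do.call(train_config, meta$config[c("batch_size", "epochs",
                                                "learning_rate", "seed")])
  rm_ <- function(name) as.matrix(utils::read.table(
    file.path(dir, paste0(name, ".csv")), sep = ","))
  layers <- lapply(seq_along(spec$hidden), function(i) {
    W <- unname(rm_(sprintf("layer%d_W", i)))
    v <- unname(rm_(sprintf("layer%d_vec", i)))
    list(W = W, b = v[1, ], gamma = v[2, ], beta = v[3, ],
         run_mean = v[4, ], run_var = v[5, ])
  })
  params <- list(layers = layers,
                 out = list(W = unname(rm_("out_W")),
                            b = as.numeric(unname(rm_("out_b")))))
  history <- tibble::as_tibble(utils::read.csv(file.path(dir, "history.csv")))
  structure(list(params = params, spec = spec, config = config,
                 history = history),
            class = "dsr_model")
}
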