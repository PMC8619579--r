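# End-to-end convenience wrappers over the module functions: preprocessing a
# study, extracting latent trajectories per condition, attractor-axis feature
# tables, plane-angle tables and dimensionality summaries.

#' Standard preprocessing of one recording
#'
#' 0.5-30 Hz zero-phase FIR band-pass followed by average re-referencing.
#'
#' @param rec A `recording`.
#' @param lo,hi Band edges in Hz.
#' @return The preprocessed `recording`.
#' @export
preprocess_recording <- function(rec, lo = 0.5, hi = 30) {
  average_rereference(bandpass(rec, lo, hi))
}

study_state <- function(config, label) {
  for (s in config$states) if (s$label == label) return(s)
  stopf("condition '%s' not found in the study config", label)
}

# Latent trajectory (n x 3) of one recording: either the generator's
# ground-truth readout or the top-3 posterior means of a trained VAE.
recording_latent <- function(rec, study, subject, method, vae_model = NULL) {
  if (method == "unmix") {
    latent_from_recording(rec, study$config, subject)
  } else {
    latent_trajectory(vae_model, rec, top_k = 3L,
                      subject_id = rec$subject_id, condition = rec$condition)$Z
  }
}

subject_index <- function(study, rec) {
  ids <- unique(vapply(study$recordings, function(r) r$subject_id, character(1)))
  match(rec$subject_id, ids)
}

train_subject_vae <- function(study, subject, recs, J = 4L, hidden = 32L,
                              n_epochs = 12L, learning_rate = 1e-3,
                              optimizer = "adam", seed = 1L) {
  X <- do.call(cbind, lapply(recs, function(r) r$data))
  m <- init_vae(nrow(X), J = J, hidden = hidden, seed = seed + subject)
  train_vae(m, X, n_epochs = n_epochs, batch_size = 20L,
            learning_rate = learning_rate, optimizer = optimizer,
            seed = seed + 100L + subject)
}

#' Per-epoch attractor-axis features of a synthetic study
#'
#' For every (subject, condition) recording: preprocess (band-pass + average
#' reference), segment into epochs, obtain the 3-D latent trajectory of each
#' epoch, fit its plane, project, and fit the elliptic attractor. The
#' `"unmix"` route uses the generator's ground-truth orthonormal readout, so
#' axes are recovered in the latent units of the state specification; the
#' `"vae"` route trains one VAE per subject on its pooled conditions and uses
#' the top-3 latent posterior means (axes then live in VAE latent units,
#' which are condition-separable but not in state-spec units).
#'
#' @param study An `acu_study`.
#' @param method `"unmix"` or `"vae"`.
#' @param epoch_len_s Epoch length in seconds.
#' @param preprocess Apply [preprocess_recording()] first.
#' @param J,n_epochs,learning_rate,optimizer,seed VAE-route training settings.
#' @return A [feature_table()] `data.frame` with columns `subject`,
#'   `condition`, `trial`, `long_axis`, `short_axis`, `plane_residual`.
#' @export
extract_axis_features <- function(study, method = c("unmix", "vae"),
                                  epoch_len_s = 10, preprocess = TRUE,
                                  J = 4L, n_epochs = 12L, learning_rate = 1e-3,
                                  optimizer = "adam", seed = 1L) {
  stopifnot(inherits(study, "acu_study"))
  method <- match.arg(method)
  rows <- list()
  ids <- unique(vapply(study$recordings, function(r) r$subject_id, character(1)))
  for (s in seq_along(ids)) {
    recs <- Filter(function(r) r$subject_id == ids[s], study$recordings)
    if (preprocess) recs <- lapply(recs, preprocess_recording)
    vm <- if (method == "vae") {
      train_subject_vae(study, s, recs, J = J, n_epochs = n_epochs,
                        learning_rate = learning_rate, optimizer = optimizer,
                        seed = seed)
    } else NULL
    for (rec in recs) {
      eps <- segment(rec, epoch_len_s)
      for (k in seq_along(eps$epochs)) {
        ep_rec <- recording(eps$epochs[[k]], rec$fs, rec$channel_labels,
                            rec$subject_id, rec$condition)
        lat <- recording_latent(ep_rec, study, s, method, vm)
        pl <- fit_plane(lat)
        fit <- fit_ellipse(project_to_plane(lat, pl))
        rows[[length(rows) + 1L]] <- data.frame(
          subject = rec$subject_id, condition = rec$condition, trial = k,
          long_axis = fit$long_axis, short_axis = fit$short_axis,
          plane_residual = pl$residual_frac)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  feature_table(out)
}

#' Inter-plane angles of a study relative to the pre-acupuncture reference
#'
#' Fits one plane per (subject, condition) to the full-recording latent
#' trajectory; the subject's reference plane is the condition with
#' manipulation frequency 0. Returns the unsigned dihedral angle of every
#' condition's plane to that reference.
#'
#' @inheritParams extract_axis_features
#' @return `data.frame` with columns `subject`, `condition`, `manip_freq`,
#'   `angle_deg`.
#' @export
plane_angle_table <- function(study, method = c("unmix", "vae"),
                              preprocess = TRUE, J = 4L, n_epochs = 12L,
                              learning_rate = 1e-3, optimizer = "adam",
                              seed = 1L) {
  stopifnot(inherits(study, "acu_study"))
  method <- match.arg(method)
  freqs <- vapply(study$config$states, function(s) s$manip_freq, numeric(1))
  ref_label <- study$config$states[[which.min(freqs)]]$label
  ids <- unique(vapply(study$recordings, function(r) r$subject_id, character(1)))
  rows <- list()
  for (s in seq_along(ids)) {
    recs <- Filter(function(r) r$subject_id == ids[s], study$recordings)
    if (preprocess) recs <- lapply(recs, preprocess_recording)
    vm <- if (method == "vae") {
      train_subject_vae(study, s, recs, J = J, n_epochs = n_epochs,
                        learning_rate = learning_rate, optimizer = optimizer,
                        seed = seed)
    } else NULL
    planes <- lapply(recs, function(r) {
      fit_plane(recording_latent(r, study, s, method, vm))
    })
    labels <- vapply(recs, function(r) r$condition, character(1))
    ref <- planes[[match(ref_label, labels)]]
    for (i in seq_along(recs)) {
      st <- study_state(study$config, labels[i])
      rows[[length(rows) + 1L]] <- data.frame(
        subject = ids[s], condition = labels[i], manip_freq = st$manip_freq,
        angle_deg = plane_angle(planes[[i]], ref))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Broadband dimensionality summary of a study
#'
#' Preprocesses each recording, computes the per-epoch broadband (and
#' optionally per-band) participation-ratio dimensionality, and returns the
#' stacked table.
#'
#' @param study An `acu_study`.
#' @param bands List of `band_definition`, or `NULL` for broadband only.
#' @param epoch_len_s Epoch length in seconds.
#' @return `data.frame` as from [band_dimensionality()], all recordings
#'   stacked.
#' @export
study_dimensionality <- function(study, bands = NULL, epoch_len_s = 10) {
  stopifnot(inherits(study, "acu_study"))
  rows <- lapply(study$recordings, function(rec) {
    band_dimensionality(preprocess_recording(rec),
                        bands = if (is.null(bands)) list() else bands,
                        epoch_len_s = epoch_len_s, broadband = TRUE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
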