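# End-to-end one-trial object-place recall: entorhinal input -> dentate ->
# mossy fibers -> CA3 attractor -> CA1 readout, with perforant-path cued
# recall and a two-alternative behavioural decision. Models the task in
# which two objects are each shown at one of two places and, given one
# object as a recall cue, the place where it appeared must be recalled.

#' Configuration for the object-place recall experiment
#'
#' @param n_ec entorhinal input units (object units + place units; the two
#'   sub-populations are each `n_ec / 2`).
#' @param n_dg dentate granule units.
#' @param n_ca3 CA3 units.
#' @param n_ca1 CA1 units.
#' @param a_dg,a_ca3,a_ca1 sparseness per stage.
#' @param C_rc recurrent contacts per CA3 unit.
#' @param n_mf mossy-fiber contacts per CA3 unit (default 46).
#' @param n_trials number of one-shot trials.
#' @param cue_type `"object"` (default: recall the place from the object) or
#'   `"full"` (cue with the entire stored event).
#' @param pp_gain relative strength of the perforant-path drive on CA3 at
#'   storage time (weak: the mossy fibers dominate storage).
#' @param storage_noise_sd s.d. of intrinsic CA3 activation noise during
#'   storage; with the mossy fibers lesioned, this noise dominates the weak
#'   pp drive and the storage-time pattern is not reproducible.
#' @param lesion character vector, any of `"mf_storage"`, `"mf_recall"`,
#'   `"pp_recall"`, `"learning"` — pathway knockouts for the consistency
#'   experiments.
#' @return object of class `object_place_config`.
#' @export
object_place_config <- function(n_ec = 400, n_dg = 600, n_ca3 = 500,
                                n_ca1 = 300,
                                a_dg = 0.05, a_ca3 = 0.05, a_ca1 = 0.1,
                                C_rc = 150, n_mf = 46,
                                n_trials = 20, cue_type = c("object", "full"),
                                pp_gain = 0.1, storage_noise_sd = 0.5,
                                lesion = character(0)) {
  cue_type <- match.arg(cue_type)
  stopifnot(n_ec %% 2 == 0, C_rc < n_ca3, n_mf <= n_dg)
  bad <- setdiff(lesion, c("mf_storage", "mf_recall", "pp_recall", "learning"))
  if (length(bad)) stop("unknown lesion(s): ", paste(bad, collapse = ", "))
  structure(
    list(n_ec = n_ec, n_dg = n_dg, n_ca3 = n_ca3, n_ca1 = n_ca1,
         a_dg = a_dg, a_ca3 = a_ca3, a_ca1 = a_ca1,
         C_rc = C_rc, n_mf = n_mf, n_trials = n_trials, cue_type = cue_type,
         pp_gain = pp_gain, storage_noise_sd = storage_noise_sd,
         lesion = lesion),
    class = "object_place_config"
  )
}

#' Train the CA1 heteroassociative readout
#'
#' Associatively modifiable feedforward (Schaffer-collateral-like) weights
#' mapping each CA3 pattern to its CA1 target pattern; recall through them
#' is a single weighted sum followed by k-WTA at the CA1 sparseness.
#'
#' @param ca3_patterns,ca1_targets matrices with one paired pattern per row.
#' @param learn_rate Hebbian step.
#' @return weight matrix (`n_ca1` x `n_ca3`).
#' @export
train_ca1_readout <- function(ca3_patterns, ca1_targets, learn_rate = 1) {
  ca3_patterns <- as_pattern_matrix(ca3_patterns)
  ca1_targets <- as_pattern_matrix(ca1_targets)
  if (nrow(ca3_patterns) != nrow(ca1_targets)) {
    stop("CA3 and CA1 pattern counts differ")
  }
  learn_rate * crossprod(ca1_targets, ca3_patterns)
}

#' Recall a CA1 pattern through the readout
#'
#' @param W_sc weights from [train_ca1_readout()].
#' @param ca3_pattern CA3 rate vector.
#' @param a_ca1 CA1 sparseness target.
#' @return binary CA1 pattern.
#' @export
recall_via_ca1 <- function(W_sc, ca3_pattern, a_ca1 = 0.1) {
  stopifnot(ncol(W_sc) == length(ca3_pattern))
  kwta(as.numeric(W_sc %*% ca3_pattern), n_active(a_ca1, nrow(W_sc)))
}

# Storage-time CA3 pattern: strong mossy-fiber drive (if intact) plus weak
# perforant-path drive plus intrinsic noise, binarized by k-WTA. Without MF
# the weak pp drive is swamped by the noise, so repeated draws during the
# same storage episode give unrelated patterns — storage fails not because
# nothing is learned but because the learned associations are inconsistent.
storage_ca3_state <- function(ec, dg, proj_mf, W_pp_fixed, cfg, mf_on) {
  drive <- numeric(cfg$n_ca3)
  if (mf_on) {
    drive <- drive +
      rowSums(matrix(dg[proj_mf$contacts], nrow = cfg$n_ca3)) + proj_mf$jitter
  }
  drive <- drive + cfg$pp_gain * as.numeric(W_pp_fixed %*% ec)
  drive <- drive + stats::rnorm(cfg$n_ca3, sd = cfg$storage_noise_sd)
  kwta(drive, n_active(cfg$a_ca3, cfg$n_ca3))
}

#' Run the one-trial object-place recall task
#'
#' Per trial: two events (object 1 at place 1, object 2 at place 2) are each
#' stored once — the dentate/mossy route sets the CA3 pattern, the CA3
#' recurrent collaterals associate it with itself, the perforant path learns
#' EC to CA3, and the CA1 readout learns CA3 to the place code. At recall,
#' one object alone is presented as the EC cue; the perforant path produces
#' a partial CA3 cue, the CA3 attractor completes it, the CA1 readout maps
#' it to a place representation, and the behavioural response is the
#' two-alternative argmax over the two place codes. A trial is correct when
#' the decoded place is the one where the cued object was stored.
#'
#' @param config an [object_place_config()].
#' @param seed integer seed.
#' @return list with `trials` (data frame: trial, cue_object, stored_place,
#'   decoded_place, correct, ca3_overlap, ca1_overlap, seed) and `accuracy`.
#' @export
run_object_place_task <- function(config, seed = NULL) {
  cfg <- config
  stopifnot(inherits(cfg, "object_place_config"))
  n_obj_units <- cfg$n_ec / 2
  learning_on <- !("learning" %in% cfg$lesion)
  with_seed(seed, {
    # Fixed anatomy shared by all trials.
    con <- build_diluted_connectivity(cfg$n_ca3, cfg$C_rc)
    net <- ca3_network(con, a_target = cfg$a_ca3, max_steps = 15)
    W_dg <- matrix(stats::runif(cfg$n_dg * cfg$n_ec), cfg$n_dg, cfg$n_ec)
    proj_mf <- mossy_projection(cfg$n_dg, cfg$n_ca3, cfg$n_mf)
    W_pp_fixed <- matrix(stats::runif(cfg$n_ca3 * cfg$n_ec, 0, 0.1),
                         cfg$n_ca3, cfg$n_ec)  # untrained pp efficacies
    ca1_place_map <- matrix(stats::runif(cfg$n_ca1 * (cfg$n_ec / 2)),
                            cfg$n_ca1, cfg$n_ec / 2)
    rows <- vector("list", cfg$n_trials)
    for (t in seq_len(cfg$n_trials)) {
      ev <- generate_events(2, 2, n_object_units = n_obj_units,
                            n_place_units = cfg$n_ec / 2,
                            object_sparseness = 0.1, place_sparseness = 0.1)
      # CA1 place codes for the two places (fixed random map + k-WTA).
      ca1_places <- t(apply(ev$places, 1L, function(pl) {
        kwta(as.numeric(ca1_place_map %*% pl), n_active(cfg$a_ca1, cfg$n_ca1))
      }))
      # --- storage (one shot per event) ---
      W_rc <- matrix(0, cfg$n_ca3, cfg$n_ca3)
      W_pp <- matrix(0, cfg$n_ca3, cfg$n_ec)
      W_sc <- matrix(0, cfg$n_ca1, cfg$n_ca3)
      ca3_stored <- matrix(0, 2, cfg$n_ca3)
      mf_on <- !("mf_storage" %in% cfg$lesion)
      for (e in 1:2) {
        ec <- ev$patterns[e, ]
        dg <- kwta(as.numeric(W_dg %*% ec), n_active(cfg$a_dg, cfg$n_dg))
        # The storage episode extends over time: each plastic pathway sees
        # its own snapshot of the CA3 state. With MF drive the snapshots
        # coincide (the pattern is imposed); without it the weak pp drive is
        # swamped by intrinsic noise and the snapshots are unrelated, so the
        # learned associations are mutually inconsistent.
        ca3_a <- storage_ca3_state(ec, dg, proj_mf, W_pp_fixed, cfg, mf_on)
        ca3_b <- storage_ca3_state(ec, dg, proj_mf, W_pp_fixed, cfg, mf_on)
        ca3_c <- storage_ca3_state(ec, dg, proj_mf, W_pp_fixed, cfg, mf_on)
        ca3_stored[e, ] <- ca3_a
        if (learning_on) {
          W_rc <- store_patterns(net, ca3_a, rule = "covariance",
                                 a_pre = cfg$a_ca3, a_post = cfg$a_ca3,
                                 weights = W_rc)
          W_pp <- W_pp + train_pp_cue(ec, ca3_b)
          place_id <- ev$events$place_id[e]
          W_sc <- W_sc + train_ca1_readout(ca3_c, ca1_places[place_id, ])
        }
      }
      # --- recall ---
      cue_obj <- sample(1:2, 1)
      ec_cue <- numeric(cfg$n_ec)
      ec_cue[seq_len(n_obj_units)] <- ev$objects[cue_obj, ]
      if (cfg$cue_type == "full") ec_cue <- ev$patterns[cue_obj, ]
      if ("pp_recall" %in% cfg$lesion) {
        ca3_cue <- numeric(cfg$n_ca3)
      } else {
        ca3_cue <- apply_pp_cue(W_pp, ec_cue, a_ca3 = cfg$a_ca3)
      }
      # ("mf_recall" removes nothing from this path: the mossy fibers play
      # no role at recall, which is the storage/recall asymmetry claim.)
      res <- recall(net, W_rc, ca3_cue)
      ca3_recalled <- res$pattern
      ca1_out <- recall_via_ca1(W_sc, ca3_recalled, a_ca1 = cfg$a_ca1)
      sims <- as.numeric(ca1_places %*% ca1_out)
      decoded_place <- if (sims[1] == sims[2]) sample(1:2, 1) else
        which.max(sims)
      stored_place <- ev$events$place_id[cue_obj]
      ca3_ov <- tryCatch(pattern_overlap(ca3_recalled, ca3_stored[cue_obj, ]),
                         error = function(e) NA_real_)
      ca1_ov <- tryCatch(
        pattern_overlap(ca1_out, ca1_places[stored_place, ]),
        error = function(e) NA_real_)
      rows[[t]] <- data.frame(
        trial = t, cue_object = cue_obj, stored_place = stored_place,
        decoded_place = decoded_place,
        correct = decoded_place == stored_place,
        ca3_overlap = ca3_ov, ca1_overlap = ca1_ov,
        seed = if (is.null(seed)) NA_integer_ else seed
      )
    }
    trials <- do.call(rbind, rows)
    list(trials = trials, accuracy = mean(trials$correct))
  })
}
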