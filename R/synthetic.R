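#' Default planted effect sizes for progressing voxels
#'
#' Mean shifts (in arbitrary normalized-signal units, against a spatially
#' correlated noise floor of sd `noise_sd`, default 0.15) added to each
#' channel over each progression class. The ordering encodes the
#' biology the pipeline is meant to recover: metabolic indices (CNI,
#' CCrI) and the normalized FLAIR signal carry the strongest infiltration
#' signal, ADC is modestly elevated, FA mildly reduced, lipid rises only
#' where enhancement will appear, and lactate carries no signal.
#'
#' @return Tibble with columns `channel`, `class`, `shift`.
#' @export
default_effect_table <- function() {
  classes <- c("NAV_to_NEL", "NAV_to_CEL", "NEL_to_CEL")
  base <- c(
    cni = 0.25, ccri = 0.25, nflair = 0.25, nadc = 0.12, nfa = -0.06,
    ncho = 0.15, nnaa = -0.12, ncre = 0.08, nlac = 0, nlip = 0,
    crni = 0.10, nt1c = 0.02, nt1 = 0.04
  )
  tab <- tidyr::expand_grid(channel = names(base), class = classes)
  tab$shift <- base[tab$channel]
  # lipid and T1c presage enhancement: shifted only in the to-CEL classes
  tab$shift[tab$channel == "nlip" & tab$class != "NAV_to_NEL"] <- 0.12
  tab$shift[tab$channel == "nt1c" & tab$class != "NAV_to_NEL"] <- 0.10
  tab
}

#' Specification of a synthetic cohort
#'
#' Bundles every knob of the generator: grid geometry, the lesion-volume
#' law (log-normal in cm^3, median 26.4 by default), treatment-cohort
#' mix, the progression-time law (log-normal, median 7 months), planted
#' per-channel effect sizes, anisotropic growth extents, noise level and
#' MRSI coverage. All randomness derives from `seed`.
#'
#' @param n_cases number of cases.
#' @param grid_shape voxel grid triple.
#' @param spacing voxel size in mm.
#' @param channels channel names to synthesize (subset of the 13 known).
#' @param lesion_volume_meanlog,lesion_volume_sdlog log-normal law of the
#'   pre-RT T2L volume in cm^3.
#' @param cel_fraction_range per-case fraction of the T2L that enhances.
#' @param cohort_mix named proportions of SOC/ATT/ENZA labels (sums to 1).
#' @param progression_time_meanlog,progression_time_sdlog log-normal law
#'   of time-to-progression in months.
#' @param threshold_months early/late boundary; late progressors get
#'   attenuated effects.
#' @param late_attenuation multiplier on effect sizes for late progressors.
#' @param effect_table tibble (channel, class, shift); must cover every
#'   generated channel for each progression class.
#' @param effect_scale global multiplier on all planted shifts.
#' @param noise_sd per-voxel sd of the spatially correlated channel noise.
#' @param noise_smooth_vox correlation length (Gaussian sigma, voxels).
#' @param growth_base_mm isotropic component of progression growth.
#' @param growth_extra_mm_range range of the per-case directional growth
#'   extent of the T2L (drawn uniformly); with the default band of 40 mm,
#'   growth never leaves the band, while a minority of cases progress
#'   beyond a 20 mm margin.
#' @param cel_growth_scale named per-cohort multiplier converting T2L
#'   growth into CEL growth; anti-angiogenic cohorts (ATT/ENZA) are
#'   biased toward non-enhancing progression.
#' @param mrsi_box_fraction per-axis fraction of the brain bounding box
#'   covered by the PRESS box (centred on the lesion).
#' @param seed integer seed.
#' @export
cohort_spec <- function(n_cases = 40,
                        grid_shape = c(48, 48, 48),
                        spacing = c(3, 3, 3),
                        channels = c("nt1c", "nt1", "nflair", "nadc", "nfa",
                                     "ncho", "ncre", "nnaa", "nlac", "nlip",
                                     "cni", "ccri", "crni"),
                        lesion_volume_meanlog = log(26.4),
                        lesion_volume_sdlog = 0.73,
                        cel_fraction_range = c(0.3, 0.6),
                        cohort_mix = c(SOC = 44 / 101, ATT = 27 / 101, ENZA = 30 / 101),
                        progression_time_meanlog = log(7),
                        progression_time_sdlog = 0.6,
                        threshold_months = 7,
                        late_attenuation = 0.4,
                        effect_table = default_effect_table(),
                        effect_scale = 1,
                        noise_sd = 0.15,
                        noise_smooth_vox = 2,
                        growth_base_mm = 4,
                        growth_extra_mm_range = c(8, 26),
                        cel_growth_scale = c(SOC = 0.6, ATT = 0.3, ENZA = 0.35),
                        mrsi_box_fraction = 0.6,
                        seed = 1) {
  if (abs(sum(cohort_mix) - 1) > 1e-8) stop("`cohort_mix` must sum to 1")
  if (is.null(names(cohort_mix))) stop("`cohort_mix` must be named")
  known <- c("nt1c", "nt1", "nflair", "nadc", "nfa", "ncho", "ncre", "nnaa",
             "nlac", "nlip", "cni", "ccri", "crni")
  if (!all(channels %in% known)) {
    stop("unknown channel(s): ", paste(setdiff(channels, known), collapse = ", "))
  }
  need <- tidyr::expand_grid(channel = channels,
                             class = c("NAV_to_NEL", "NAV_to_CEL", "NEL_to_CEL"))
  have <- paste(effect_table$channel, effect_table$class)
  miss <- !(paste(need$channel, need$class) %in% have)
  if (any(miss)) {
    stop("effect_table misses entries, e.g. ",
         paste(utils::head(paste(need$channel[miss], need$class[miss]), 3),
               collapse = "; "))
  }
  spec <- list(
    n_cases = as.integer(n_cases), grid_shape = as.integer(grid_shape),
    spacing = as.numeric(spacing), channels = channels,
    lesion_volume_meanlog = lesion_volume_meanlog,
    lesion_volume_sdlog = lesion_volume_sdlog,
    cel_fraction_range = cel_fraction_range,
    cohort_mix = cohort_mix,
    progression_time_meanlog = progression_time_meanlog,
    progression_time_sdlog = progression_time_sdlog,
    threshold_months = threshold_months,
    late_attenuation = late_attenuation,
    effect_table = effect_table, effect_scale = effect_scale,
    noise_sd = noise_sd, noise_smooth_vox = noise_smooth_vox,
    growth_base_mm = growth_base_mm,
    growth_extra_mm_range = growth_extra_mm_range,
    cel_growth_scale = cel_growth_scale,
    mrsi_box_fraction = mrsi_box_fraction,
    seed = as.integer(seed)
  )
  structure(spec, class = "cohort_spec")
}

# deterministic integer seed for case i, kept under 2^31
case_seed <- function(spec, case_index) {
  as.integer((as.numeric(spec$seed) * 48271 + case_index * 9973) %% 2147483399)
}

# largest-remainder allocation of cohort labels, interleaved for balance
cohort_labels <- function(spec) {
  n <- spec$n_cases
  mix <- spec$cohort_mix
  base <- floor(mix * n)
  rem <- mix * n - base
  extra <- order(rem, decreasing = TRUE)[seq_len(n - sum(base))]
  counts <- base
  counts[extra] <- counts[extra] + 1
  # deterministic interleave so every prefix is roughly proportional
  pool <- counts
  out <- character(n)
  frac <- rep(0, length(mix))
  for (i in seq_len(n)) {
    frac <- frac + mix
    cand <- which(pool > 0)
    pick <- cand[which.max(frac[cand])]
    frac[pick] <- frac[pick] - 1
    pool[pick] <- pool[pick] - 1
    out[i] <- names(mix)[pick]
  }
  out
}

# physical voxel-centre coordinate arrays for a grid
coord_arrays <- function(shape, spacing) {
  ax <- lapply(1:3, function(a) (seq_len(shape[a]) - 0.5) * spacing[a])
  list(
    x = array(rep(ax[[1]], times = shape[2] * shape[3]), shape),
    y = array(rep(rep(ax[[2]], each = shape[1]), times = shape[3]), shape),
    z = array(rep(ax[[3]], each = shape[1] * shape[2]), shape)
  )
}

ellipsoid_mask <- function(co, centre, semi, spacing, shape) {
  v <- ((co$x - centre[1]) / semi[1])^2 +
    ((co$y - centre[2]) / semi[2])^2 +
    ((co$z - centre[3]) / semi[3])^2
  vol_grid(array(as.numeric(v <= 1), shape), spacing)
}

random_unit_vec <- function() {
  v <- stats::rnorm(3)
  v / sqrt(sum(v^2))
}

# smoothed white noise rescaled to a target sd
correlated_noise <- function(shape, spacing, sigma_vox, sd_target) {
  w <- vol_grid(array(stats::rnorm(prod(shape)), shape), spacing)
  s <- smooth_field(w, sigma_vox)
  sdv <- stats::sd(s$values)
  s$values <- s$values / sdv * sd_target
  s
}

# baseline level and fixed tissue offsets per channel (pre-RT appearance);
# these make the lesion visible on the channels the way the transition
# shifts make future progression visible.
channel_baseline <- function() {
  list(
    level = c(nt1c = 0.5, nt1 = 0.5, nflair = 0.5, nadc = 0.5, nfa = 0.6,
              ncho = 0.5, ncre = 0.5, nnaa = 0.6, nlac = 0.4, nlip = 0.4,
              cni = 0.3, ccri = 0.3, crni = 0.3),
    cel = c(nt1c = 0.8, nt1 = 0.1, nflair = 0.6, nadc = 0.25, nfa = -0.2,
            ncho = 0.5, ncre = 0.2, nnaa = -0.3, nlac = 0.2, nlip = 0.3,
            cni = 0.7, ccri = 0.6, crni = 0.3),
    nel = c(nt1c = 0.1, nt1 = 0.05, nflair = 0.7, nadc = 0.3, nfa = -0.15,
            ncho = 0.35, ncre = 0.15, nnaa = -0.2, nlac = 0.1, nlip = 0.1,
            cni = 0.5, ccri = 0.45, crni = 0.2),
    cavity = c(nt1c = -0.3, nt1 = -0.3, nflair = -0.2, nadc = 0.4, nfa = -0.3,
               ncho = -0.2, ncre = -0.2, nnaa = -0.3, nlac = 0, nlip = 0,
               cni = -0.1, ccri = -0.1, crni = -0.1),
    ventricles = c(nt1c = -0.2, nt1 = -0.25, nflair = -0.3, nadc = 0.45,
                   nfa = -0.35, ncho = -0.2, ncre = -0.2, nnaa = -0.3,
                   nlac = 0, nlip = 0, cni = -0.1, ccri = -0.1, crni = -0.1)
  )
}

#' Generate one synthetic pre-RT / progression case pair
#'
#' Builds an ellipsoidal brain with ventricles, a resection cavity
#' adjacent to the lesion, smoothed random-blob pre-RT CEL/T2L masks,
#' anisotropically grown progression masks (per-case preferred direction,
#' bounded so no progression leaves the 4 cm band), and multi-parametric
#' channels = tissue baseline + planted transition-class shifts +
#' spatially correlated noise. Metabolic channels only carry signal
#' inside the PRESS-box coverage mask. Anti-angiogenic cohorts (ATT,
#' ENZA) get proportionally less enhancing growth; late progressors
#' (time-to-progression at or beyond the threshold) get attenuated
#' effect sizes.
#'
#' @param spec a [cohort_spec()].
#' @param case_index 1-based case number within the cohort.
#' @return A `case_record` list: `case_id`, `cohort`,
#'   `time_to_progression`, `channels`, `pre_masks`, `prog_masks`,
#'   `mrsi_coverage`.
#' @export
generate_case <- function(spec, case_index) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(case_seed(spec, case_index))
  shape <- spec$grid_shape
  sp <- spec$spacing
  extent <- shape * sp
  centre <- extent / 2
  co <- coord_arrays(shape, sp)
  voxvol <- prod(sp)

  # brain and ventricles
  semi <- c(0.46, 0.40, 0.36) * extent * stats::runif(3, 0.97, 1.03)
  brain <- ellipsoid_mask(co, centre, semi, sp, shape)
  vent <- mask_union(
    ellipsoid_mask(co, centre + c(0, 10, 0), c(8, 20, 10), sp, shape),
    ellipsoid_mask(co, centre + c(0, -10, 0), c(8, 20, 10), sp, shape)
  )
  vent <- mask_intersect(vent, brain)

  ok <- FALSE
  for (attempt in 1:10) {
    # lesion volume and centre
    v_t2l_cm3 <- stats::rlnorm(1, spec$lesion_volume_meanlog,
                               spec$lesion_volume_sdlog)
    k_target <- max(10L, as.integer(round(v_t2l_cm3 * 1000 / voxvol)))
    dir_les <- random_unit_vec()
    c_les <- centre + 0.45 * semi * dir_les
    r0 <- (3 * v_t2l_cm3 * 1000 / (4 * pi))^(1 / 3)
    d_les <- sqrt((co$x - c_les[1])^2 + (co$y - c_les[2])^2 + (co$z - c_les[3])^2)

    # cavity adjacent to the lesion, pulled toward the brain centre
    c_cav <- c_les + (centre - c_les) / sqrt(sum((centre - c_les)^2)) * (0.7 * r0)
    cavity <- ellipsoid_mask(co, c_cav, rep(max(4, 0.45 * r0), 3), sp, shape)
    cavity <- mask_intersect(cavity, brain)

    # blob field: radial profile + correlated noise, thresholded at the
    # target voxel count among eligible voxels
    noise <- correlated_noise(shape, sp, 2.5, 0.35)
    field <- (1 - d_les / r0) + noise$values
    eligible <- brain$values > 0.5 & vent$values <= 0.5 & cavity$values <= 0.5
    if (sum(eligible) <= k_target) next # lesion larger than brain: resample
    thr <- sort(field[eligible], decreasing = TRUE)[k_target]
    t2l <- new_like(brain, as.numeric(eligible & field >= thr))
    comp <- label_mask_components(t2l, 26)
    if (max(comp$values) > 0) {
      biggest <- which.max(tabulate(comp$values[comp$values > 0]))
      t2l$values[] <- as.numeric(comp$values == biggest)
    }
    if (n_voxels(t2l) < 0.5 * k_target || n_voxels(t2l) < 10) next

    # enhancing sub-blob inside the T2L
    cel_frac <- stats::runif(1, spec$cel_fraction_range[1], spec$cel_fraction_range[2])
    k_cel <- max(5L, as.integer(round(cel_frac * n_voxels(t2l))))
    f_cel <- field + correlated_noise(shape, sp, 2, 0.25)$values
    in_t2l <- t2l$values > 0.5
    thr_c <- sort(f_cel[in_t2l], decreasing = TRUE)[min(k_cel, sum(in_t2l))]
    cel <- new_like(brain, as.numeric(in_t2l & f_cel >= thr_c))
    if (n_voxels(cel) >= 5) { ok <- TRUE; break }
  }
  if (!ok) stop("case generation failed after bounded retries")

  # cohort label, progression time, growth extents
  cohort <- cohort_labels(spec)[case_index]
  ttp <- stats::rlnorm(1, spec$progression_time_meanlog,
                       spec$progression_time_sdlog)
  u <- random_unit_vec()
  extra_t2l <- stats::runif(1, spec$growth_extra_mm_range[1],
                            spec$growth_extra_mm_range[2])
  cel_scale <- spec$cel_growth_scale[[cohort]]

  # anisotropic growth: margin depends on the angle to the preferred
  # direction; bounded by base + extra < band width (40 mm)
  rel <- cbind(as.numeric(co$x - c_les[1]), as.numeric(co$y - c_les[2]),
               as.numeric(co$z - c_les[3]))
  rn <- sqrt(rowSums(rel^2))
  cosang <- as.numeric(rel %*% u) / pmax(rn, 1e-9)
  wdir <- array(pmax(0, cosang), shape)
  room <- mask_subtract(mask_subtract(brain, vent), cavity)

  d_t2l <- distance_map_mm(t2l)$values
  grow_t2l <- d_t2l <= spec$growth_base_mm + extra_t2l * wdir + 1e-9
  prog_t2l <- mask_intersect(new_like(brain, as.numeric(t2l$values > 0.5 | grow_t2l)), room)
  d_cel <- distance_map_mm(cel)$values
  grow_cel <- d_cel <= 0.5 * spec$growth_base_mm + cel_scale * extra_t2l * wdir + 1e-9
  prog_cel <- mask_intersect(new_like(brain, as.numeric(cel$values > 0.5 | grow_cel)),
                             prog_t2l)

  pre_masks <- derive_masks(cel, t2l, cavity, vent, brain)
  prog_masks <- derive_masks(prog_cel, prog_t2l, cavity, vent, brain)

  # PRESS box centred on the lesion, spanning a fraction of the brain bbox
  bidx <- which(brain$values > 0.5, arr.ind = TRUE)
  cov <- array(0, shape)
  covsel <- lapply(1:3, function(a) {
    rngv <- range(bidx[, a])
    half <- 0.5 * spec$mrsi_box_fraction * (rngv[2] - rngv[1] + 1)
    cl <- c_les[a] / sp[a] + 0.5 # lesion centre in voxel index space
    lo <- max(rngv[1], floor(cl - half))
    hi <- min(rngv[2], ceiling(cl + half))
    lo:hi
  })
  cov[covsel[[1]], covsel[[2]], covsel[[3]]] <- 1
  mrsi_coverage <- vol_grid(cov, sp)

  # transition-class masks for channel synthesis
  m_n2c <- mask_intersect(pre_masks$nav, prog_masks$cel)$values > 0.5
  m_n2n <- mask_intersect(pre_masks$nav, prog_masks$nel)$values > 0.5
  m_e2c <- mask_intersect(pre_masks$nel, prog_masks$cel)$values > 0.5
  cls_masks <- list(NAV_to_NEL = m_n2n, NAV_to_CEL = m_n2c, NEL_to_CEL = m_e2c)

  eff <- spec$effect_scale *
    (if (ttp >= spec$threshold_months) spec$late_attenuation else 1)
  bl <- channel_baseline()
  in_cel <- pre_masks$cel$values > 0.5
  in_nel <- pre_masks$nel$values > 0.5
  in_cav <- pre_masks$cavity$values > 0.5
  in_ven <- pre_masks$ventricles$values > 0.5
  in_cov <- mrsi_coverage$values > 0.5
  channels <- list()
  for (ch in spec$channels) {
    v <- array(bl$level[[ch]], shape)
    v[in_cel] <- v[in_cel] + bl$cel[[ch]]
    v[in_nel] <- v[in_nel] + bl$nel[[ch]]
    v[in_cav] <- v[in_cav] + bl$cavity[[ch]]
    v[in_ven] <- v[in_ven] + bl$ventricles[[ch]]
    for (cls in names(cls_masks)) {
      sh <- spec$effect_table$shift[spec$effect_table$channel == ch &
                                      spec$effect_table$class == cls]
      v[cls_masks[[cls]]] <- v[cls_masks[[cls]]] + eff * sh
    }
    v <- v + correlated_noise(shape, sp, spec$noise_smooth_vox, spec$noise_sd)$values
    if (ch %in% metabolic_channels()) {
      v[!in_cov] <- bl$level[[ch]] # baseline fill outside the PRESS box
    }
    channels[[ch]] <- vol_grid(v, sp)
  }

  rec <- structure(
    list(
      case_id = sprintf("case_%03d", case_index), cohort = cohort,
      time_to_progression = ttp, channels = channels,
      pre_masks = pre_masks, prog_masks = prog_masks,
      mrsi_coverage = mrsi_coverage
    ),
    class = "case_record"
  )
  assert_case_invariants(rec)
  rec
}

# hard construction guarantees, asserted on every generated case
assert_case_invariants <- function(rec) {
  stopifnot(
    sum(rec$pre_masks$cel$values > 0.5 & rec$pre_masks$t2l$values <= 0.5) == 0,
    sum(rec$prog_masks$cel$values > 0.5 & rec$prog_masks$t2l$values <= 0.5) == 0
  )
  band <- band_mask(rec$pre_masks, 40)
  prog_les <- mask_union(rec$prog_masks$t2l, rec$prog_masks$cel)
  if (sum(prog_les$values > 0.5 & band$values <= 0.5) > 0) {
    stop("internal error: progression outside the 4 cm band")
  }
  for (nm in c("cavity", "ventricles", "t2l", "cel")) {
    if (sum(rec$pre_masks[[nm]]$values > 0.5 &
            rec$pre_masks$brain$values <= 0.5) > 0) {
      stop("internal error: ", nm, " outside the brain")
    }
  }
  invisible(rec)
}

#' @export
print.case_record <- function(x, ...) {
  cat(sprintf(
    "<case_record> %s [%s], progression at %.1f months\n  T2L %d -> %d voxels, CEL %d -> %d voxels, brain %d voxels\n",
    x$case_id, x$cohort, x$time_to_progression,
    n_voxels(x$pre_masks$t2l), n_voxels(x$prog_masks$t2l),
    n_voxels(x$pre_masks$cel), n_voxels(x$prog_masks$cel),
    n_voxels(x$pre_masks$brain)
  ))
  invisible(x)
}

#' Generate a full synthetic cohort
#'
#' @param spec a [cohort_spec()].
#' @return A `cohort` list with `cases` (list of `case_record`) and a
#'   `manifest` tibble (case id, cohort label, time-to-progression,
#'   lesion volumes, per-case seed).
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  cases <- vector("list", spec$n_cases)
  for (i in seq_len(spec$n_cases)) {
    cases[[i]] <- tryCatch(generate_case(spec, i),
                           error = function(e) stop("case ", i, ": ",
                                                    conditionMessage(e)))
  }
  manifest <- purrr::map2_dfr(cases, seq_along(cases), function(cs, i) {
    tibble::tibble(
      case_id = cs$case_id, cohort = cs$cohort,
      time_to_progression = cs$time_to_progression,
      t2l_pre_cm3 = mask_volume_mm3(cs$pre_masks$t2l) / 1000,
      cel_pre_cm3 = mask_volume_mm3(cs$pre_masks$cel) / 1000,
      lesion_fraction = (n_voxels(cs$pre_masks$t2l) + n_voxels(cs$pre_masks$cel) -
                           n_voxels(mask_intersect(cs$pre_masks$t2l, cs$pre_masks$cel))) /
        n_voxels(cs$pre_masks$brain),
      seed = case_seed(spec, i)
    )
  })
  structure(list(cases = cases, manifest = manifest, spec = spec),
            class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("<cohort> %d cases on %s grids\n", length(x$cases),
              paste(x$spec$grid_shape, collapse = "x")))
  print(dplyr::count(x$manifest, .data$cohort))
  invisible(x)
}

# ---- disk layout ------------------------------------------------------

#' Write / read a case directory
#'
#' One directory per case: channels as `<name>.nii.gz`, masks as
#' `mask_<role>_<timepoint>.nii.gz` plus `mask_cavity`, `mask_ventricles`,
#' `mask_brain`, `mask_mrsi_coverage`, and a `meta.csv` sidecar with the
#' case id, cohort label and time-to-progression.
#'
#' @param case a `case_record`.
#' @param dir directory to create/read.
#' @export
write_case <- function(case, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (ch in names(case$channels)) {
    write_volume(case$channels[[ch]], file.path(dir, paste0(ch, ".nii.gz")))
  }
  write_volume(case$pre_masks$cel, file.path(dir, "mask_cel_pre.nii.gz"))
  write_volume(case$pre_masks$t2l, file.path(dir, "mask_t2l_pre.nii.gz"))
  write_volume(case$prog_masks$cel, file.path(dir, "mask_cel_prog.nii.gz"))
  write_volume(case$prog_masks$t2l, file.path(dir, "mask_t2l_prog.nii.gz"))
  write_volume(case$pre_masks$cavity, file.path(dir, "mask_cavity.nii.gz"))
  write_volume(case$pre_masks$ventricles, file.path(dir, "mask_ventricles.nii.gz"))
  write_volume(case$pre_masks$brain, file.path(dir, "mask_brain.nii.gz"))
  write_volume(case$mrsi_coverage, file.path(dir, "mask_mrsi_coverage.nii.gz"))
  utils::write.csv(
    data.frame(case_id = case$case_id, cohort = case$cohort,
               time_to_progression = case$time_to_progression),
    file.path(dir, "meta.csv"), row.names = FALSE
  )
  invisible(dir)
}

#' @rdname write_case
#' @export
read_case <- function(dir) {
  meta <- utils::read.csv(file.path(dir, "meta.csv"), stringsAsFactors = FALSE)
  rd_mask <- function(nm) read_volume(file.path(dir, paste0(nm, ".nii.gz")), mask = TRUE)
  brain <- rd_mask("mask_brain")
  cavity <- rd_mask("mask_cavity")
  vent <- rd_mask("mask_ventricles")
  pre <- derive_masks(rd_mask("mask_cel_pre"), rd_mask("mask_t2l_pre"),
                      cavity, vent, brain)
  prog <- derive_masks(rd_mask("mask_cel_prog"), rd_mask("mask_t2l_prog"),
                       cavity, vent, brain)
  chfiles <- setdiff(list.files(dir, pattern = "\\.nii\\.gz$"),
                     list.files(dir, pattern = "^mask_"))
  channels <- list()
  for (f in chfiles) {
    channels[[sub("\\.nii\\.gz$", "", f)]] <- read_volume(file.path(dir, f))
  }
  structure(
    list(case_id = meta$case_id, cohort = meta$cohort,
         time_to_progression = meta$time_to_progression,
         channels = channels, pre_masks = pre, prog_masks = prog,
         mrsi_coverage = rd_mask("mask_mrsi_coverage")),
    class = "case_record"
  )
}

#' @rdname write_case
#' @param cohort a `cohort` object.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (cs in cohort$cases) write_case(cs, file.path(dir, cs$case_id))
  utils::write.csv(cohort$manifest, file.path(dir, "manifest.csv"),
                   row.names = FALSE)
  invisible(dir)
}

#' @rdname write_case
#' @export
read_cohort <- function(dir) {
  manifest <- tibble::as_tibble(
    utils::read.csv(file.path(dir, "manifest.csv"), stringsAsFactors = FALSE)
  )
  cases <- lapply(manifest$case_id, function(id) read_case(file.path(dir, id)))
  structure(list(cases = cases, manifest = manifest, spec = NULL),
            class = "cohort")
}
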