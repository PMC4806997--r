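GYROMAGNETIC_MHZ_PER_T <- 42.577

#' Six-peak triglyceride fat spectrum
#'
#' Chemical-shift offsets of the triglyceride proton groups relative to
#' water, with published relative amplitudes (methyl, bulk methylene,
#' beta-carboxyl/allylic, alpha-carboxyl, diacyl and olefinic/glycerol
#' groups). The bulk methylene peak sits at -3.40 ppm, i.e. about -217 Hz at
#' 1.5 T. Single-peak Dixon separation treats fat as this one peak; the
#' remaining peaks dephase differently at the two echo times and part of the
#' fat signal is misassigned to water.
#'
#' @param field_T static field strength in tesla.
#' @return data.frame with columns `freq_hz` and `amp` (amplitudes sum to 1).
#' @export
fat_spectrum_six_peak <- function(field_T = 1.5) {
  ppm <- c(-3.80, -3.40, -2.60, -1.94, -0.39, 0.60)
  amp <- c(0.087, 0.693, 0.128, 0.004, 0.039, 0.048)
  data.frame(freq_hz = ppm * GYROMAGNETIC_MHZ_PER_T * field_T, amp = amp / sum(amp))
}

#' Single-peak fat spectrum
#'
#' Idealised fat model with all signal at one chemical-shift frequency. The
#' default frequency, -209.64 Hz, is the in-phase condition implied by a
#' 4.77 ms in-phase echo time (1 / 4.77 ms), so the gradient-echo presets
#' are exactly in/opposed phase under this model.
#'
#' @param freq_hz chemical-shift offset of the single peak, Hz.
#' @return data.frame with columns `freq_hz`, `amp`.
#' @export
fat_spectrum_single_peak <- function(freq_hz = -1000 / 4.77) {
  data.frame(freq_hz = freq_hz, amp = 1)
}

#' Tissue relaxation and proton-density properties
#'
#' Defaults are literature-typical values for fibroglandular tissue (water
#' compartment) and breast adipose tissue at 1.5 T; they are configurable
#' and are not measurements from any particular cohort. Relative proton
#' densities default to 1 for both species; `fat_pd` can be lowered to the
#' triglyceride-proton-density alternative used with fixed theoretical
#' correction factors.
#'
#' @param water_pd,fat_pd relative proton densities.
#' @param water_t1_ms,fat_t1_ms longitudinal relaxation times, ms.
#' @param water_t2_ms,fat_t2_ms transverse relaxation times, ms.
#' @param fat_spectrum data.frame (`freq_hz`, `amp`) as returned by
#'   [fat_spectrum_six_peak()] or [fat_spectrum_single_peak()].
#' @return a `TissueProperties` list.
#' @export
tissue_properties <- function(water_pd = 1, fat_pd = 1,
                              water_t1_ms = 1266, fat_t1_ms = 296,
                              water_t2_ms = 58, fat_t2_ms = 53,
                              fat_spectrum = fat_spectrum_six_peak()) {
  if (any(c(water_t1_ms, fat_t1_ms, water_t2_ms, fat_t2_ms) <= 0))
    stop("relaxation times must be positive")
  if (any(fat_spectrum$amp < 0) || abs(sum(fat_spectrum$amp) - 1) > 1e-8)
    stop("fat spectrum amplitudes must be non-negative and sum to 1")
  structure(list(water_pd = water_pd, fat_pd = fat_pd,
                 water_t1_ms = water_t1_ms, fat_t1_ms = fat_t1_ms,
                 water_t2_ms = water_t2_ms, fat_t2_ms = fat_t2_ms,
                 fat_spectrum = fat_spectrum),
            class = "TissueProperties")
}

#' Dixon sequence parameters
#'
#' `tau_in_ms`/`tau_out_ms` are the fat-water chemical-shift evolution times
#' of the two echoes. For a gradient echo they equal the echo times; a spin
#' echo refocuses chemical shift at the echo centre (`tau_in = 0`) and the
#' opposed image is acquired at a readout offset of half the fat-water
#' period.
#'
#' @param family `"GRE_SPGR"` or `"SE"`.
#' @param tr_ms repetition time, ms.
#' @param te_in_ms,te_out_ms echo times of the in-phase and opposed-phase
#'   echoes, ms (must differ).
#' @param flip_angle_deg excitation flip angle (GRE only).
#' @param echo_train_length,echo_spacing_ms echo-train settings (SE only).
#' @param t2_weighting_k effective-TE multiplier for the spin-echo train:
#'   `TE_eff = TE + k * echo_spacing`; `k = 0` uses the nominal TE.
#' @param tau_in_ms,tau_out_ms chemical-shift evolution times, ms; defaults
#'   follow the family as described above.
#' @param name preset name carried through for provenance.
#' @param acq_spacing_mm native acquisition voxel spacing (used by the
#'   experiment drivers when reformatting).
#' @return a `SequenceParams` list.
#' @export
sequence_params <- function(family = c("GRE_SPGR", "SE"),
                            tr_ms, te_in_ms, te_out_ms,
                            flip_angle_deg = NULL,
                            echo_train_length = NULL, echo_spacing_ms = NULL,
                            t2_weighting_k = 0,
                            tau_in_ms = NULL, tau_out_ms = NULL,
                            name = "custom",
                            acq_spacing_mm = NULL) {
  family <- match.arg(family)
  if (family == "GRE_SPGR") {
    if (is.null(flip_angle_deg)) stop("GRE_SPGR requires a flip angle")
    tau_in_ms <- tau_in_ms %||% te_in_ms
    tau_out_ms <- tau_out_ms %||% te_out_ms
  } else {
    tau_in_ms <- tau_in_ms %||% 0
    tau_out_ms <- tau_out_ms %||% (4.77 / 2)
  }
  if (te_in_ms == te_out_ms && tau_in_ms == tau_out_ms)
    stop("the two echoes must differ in echo time or chemical-shift evolution time")
  structure(list(family = family, tr_ms = tr_ms,
                 te_in_ms = te_in_ms, te_out_ms = te_out_ms,
                 flip_angle_deg = flip_angle_deg,
                 echo_train_length = echo_train_length,
                 echo_spacing_ms = echo_spacing_ms,
                 t2_weighting_k = t2_weighting_k,
                 tau_in_ms = tau_in_ms, tau_out_ms = tau_out_ms,
                 name = name, acq_spacing_mm = acq_spacing_mm),
            class = "SequenceParams")
}

#' Acquisition presets
#'
#' The three Dixon acquisitions of the study protocol at 1.5 T:
#' `"hr_gre_pd"` — high-resolution 3D spoiled gradient echo, TR 7.34 ms,
#' TE 4.77/2.39 ms, flip angle 4 degrees (proton-density weighted),
#' 1.3 x 1.3 x 1.0 mm voxels; `"hr_gre_t1"` — the same at flip angle 25
#' degrees (T1 weighted); `"lr_se_t1"` — low-resolution 2D spin echo, TR
#' 500 ms, TE 12 ms, echo train length 8, echo spacing 12.2 ms,
#' 0.8 x 0.8 x 7.0 mm voxels.
#'
#' @param name preset name.
#' @return a `SequenceParams`.
#' @export
sequence_preset <- function(name = c("hr_gre_pd", "hr_gre_t1", "lr_se_t1")) {
  name <- match.arg(name)
  switch(name,
    hr_gre_pd = sequence_params("GRE_SPGR", tr_ms = 7.34, te_in_ms = 4.77,
                                te_out_ms = 2.39, flip_angle_deg = 4,
                                name = "hr_gre_pd",
                                acq_spacing_mm = c(1.3, 1.3, 1.0)),
    hr_gre_t1 = sequence_params("GRE_SPGR", tr_ms = 7.34, te_in_ms = 4.77,
                                te_out_ms = 2.39, flip_angle_deg = 25,
                                name = "hr_gre_t1",
                                acq_spacing_mm = c(1.3, 1.3, 1.0)),
    lr_se_t1 = sequence_params("SE", tr_ms = 500, te_in_ms = 12,
                               te_out_ms = 12, echo_train_length = 8,
                               echo_spacing_ms = 12.2, t2_weighting_k = 0,
                               tau_in_ms = 0, tau_out_ms = 4.77 / 2,
                               name = "lr_se_t1",
                               acq_spacing_mm = c(0.8, 0.8, 7.0)))
}

#' Steady-state signal amplitude of one species at one echo
#'
#' Closed-form magnitudes: spoiled gradient echo
#' `PD sin(a) (1 - E1) / (1 - E1 cos(a)) exp(-TE / T2)` with
#' `E1 = exp(-TR / T1)` (T2* taken as T2: the phantom has no mesoscopic
#' field perturbers), and spin echo `PD (1 - E1) exp(-TE_eff / T2)` with
#' `TE_eff = TE + k * echo_spacing` absorbing echo-train T2 weighting.
#'
#' @param seq a `SequenceParams`.
#' @param pd,t1_ms,t2_ms species proton density and relaxation times.
#' @param te_ms echo time at which the magnitude is evaluated.
#' @return scalar signal magnitude.
#' @export
species_signal <- function(seq, pd, t1_ms, t2_ms, te_ms) {
  if (t1_ms <= 0 || t2_ms <= 0) stop("relaxation times must be positive")
  e1 <- exp(-seq$tr_ms / t1_ms)
  if (seq$family == "GRE_SPGR") {
    a <- seq$flip_angle_deg * pi / 180
    pd * sin(a) * (1 - e1) / (1 - e1 * cos(a)) * exp(-te_ms / t2_ms)
  } else if (seq$family == "SE") {
    te_eff <- te_ms + seq$t2_weighting_k * (seq$echo_spacing_ms %||% 0)
    pd * (1 - e1) * exp(-te_eff / t2_ms)
  } else stop("unknown sequence family: ", seq$family)
}

#' Complex fat phasor at a chemical-shift evolution time
#'
#' Amplitude-weighted sum `sum_m a_m exp(2 pi i f_m tau)` over the fat
#' spectrum peaks.
#'
#' @param spectrum data.frame (`freq_hz`, `amp`).
#' @param tau_ms evolution time, ms.
#' @return complex scalar.
#' @export
fat_phasor <- function(spectrum, tau_ms) {
  sum(spectrum$amp * exp(2i * pi * spectrum$freq_hz * tau_ms / 1000))
}

#' Evaluate a smooth polynomial coil-sensitivity bias field
#'
#' A low-order multiplicative bias: `1 + gx X + gy Y + gz Z + qx X^2 + ...`
#' with X, Y, Z the voxel-centre coordinates normalised to `[-1, 1]` over
#' the grid. `"none"` yields a field of ones.
#'
#' @param bias `"none"` or a named list with any of `gx, gy, gz, qx, qy, qz`.
#' @param grid_shape integer length-3.
#' @return 3D array of multiplicative factors.
#' @export
evaluate_bias_field <- function(bias, grid_shape) {
  d <- as.integer(grid_shape)
  if (identical(bias, "none") || is.null(bias)) return(array(1, dim = d))
  nrm <- function(n) if (n > 1) 2 * (seq_len(n) - 1) / (n - 1) - 1 else rep(0, n)
  X <- array(nrm(d[1]), dim = d)
  Y <- array(rep(nrm(d[2]), each = d[1]), dim = d)
  Z <- array(rep(nrm(d[3]), each = d[1] * d[2]), dim = d)
  g <- function(k) bias[[k]] %||% 0
  1 + g("gx") * X + g("gy") * Y + g("gz") * Z +
    g("qx") * X^2 + g("qy") * Y^2 + g("qz") * Z^2
}

#' Simulate a two-point Dixon acquisition of a phantom
#'
#' Produces the complex in-phase and opposed-phase echo volumes. Per voxel,
#' the water compartment (volume fraction `v`) contributes its steady-state
#' magnitude from the sequence's signal equation; the fat compartment
#' (`1 - v`) contributes its magnitude times the complex spectral phasor at
#' the echo's chemical-shift evolution time. The complex sum is multiplied
#' by the coil bias field, and independent complex Gaussian noise is added
#' to both echoes (magnitude images downstream are therefore Rician).
#' Deterministic given `rng_seed`.
#'
#' @param phantom a `Phantom`.
#' @param tissues a `TissueProperties`.
#' @param seq a `SequenceParams` or preset name.
#' @param noise_sd noise standard deviation as a fraction of the mean
#'   in-phase tissue magnitude; defaults to the phantom spec's value.
#' @param bias_field bias specification; defaults to the phantom spec's.
#' @param rng_seed seed for the noise; defaults to the phantom spec's seed.
#' @return an `EchoPair`: list with complex `in_phase` and `out_of_phase`
#'   `VolumeImage`s, the `seq` used, and `noise_sd_abs` (the absolute noise
#'   level applied).
#' @export
simulate_dixon_acquisition <- function(phantom, tissues = tissue_properties(),
                                       seq = "hr_gre_pd",
                                       noise_sd = NULL, bias_field = NULL,
                                       rng_seed = NULL) {
  stopifnot(inherits(phantom, "Phantom"))
  if (is.character(seq)) seq <- sequence_preset(seq)
  stopifnot(inherits(seq, "SequenceParams"))
  noise_sd <- noise_sd %||% phantom$spec$noise_sd
  bias_field <- bias_field %||% phantom$spec$bias_field
  rng_seed <- rng_seed %||% phantom$spec$rng_seed

  v <- phantom$v
  tissue <- phantom$labels != LABEL_BACKGROUND
  d <- dim(v)
  bias <- evaluate_bias_field(bias_field, d)

  echo <- function(te_ms, tau_ms) {
    sw <- species_signal(seq, tissues$water_pd, tissues$water_t1_ms,
                         tissues$water_t2_ms, te_ms)
    sf <- species_signal(seq, tissues$fat_pd, tissues$fat_t1_ms,
                         tissues$fat_t2_ms, te_ms)
    ph <- fat_phasor(tissues$fat_spectrum, tau_ms)
    sig <- array(0i, dim = d)
    sig[tissue] <- v[tissue] * sw + (1 - v[tissue]) * sf * ph
    sig * bias
  }
  ip <- echo(seq$te_in_ms, seq$tau_in_ms)
  op <- echo(seq$te_out_ms, seq$tau_out_ms)

  noise_abs <- 0
  if (noise_sd > 0) {
    noise_abs <- noise_sd * mean(Mod(ip[tissue]))
    set.seed(rng_seed)
    n <- prod(d)
    ip <- ip + complex(real = stats::rnorm(n, 0, noise_abs),
                       imaginary = stats::rnorm(n, 0, noise_abs))
    op <- op + complex(real = stats::rnorm(n, 0, noise_abs),
                       imaginary = stats::rnorm(n, 0, noise_abs))
  }
  structure(list(in_phase = volume_image(ip, phantom$spacing_mm),
                 out_of_phase = volume_image(op, phantom$spacing_mm),
                 seq = seq, noise_sd_abs = noise_abs),
            class = "EchoPair")
}
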