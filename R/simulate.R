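#' Parameters of the read-position simulator
#'
#' Describes a mixture over read start positions with the four components
#' seen in vesicle-DNA coverage profiles: a uniform background, a
#' *dif*-centred over-replication peak, a linear ori-to-ter replication
#' gradient (the signature of DNA from exponentially replicating cells),
#' and a localized phage hotspot. Component weights must satisfy
#' `pi_ter + pi_grad + pi_phage <= 1`; the remainder is background.
#'
#' The peak kernel is symmetric around `peak_center` unless
#' `peak_asymmetry > 0`, which moves mass to the right flank (fraction
#' `0.5 + peak_asymmetry/2`). `peak_width_bp` is the full support width
#' for the rectangular and triangular kernels; for the Laplace kernel the
#' scale is `peak_width_bp / 8`, putting about 98% of the mass within the
#' nominal width.
#'
#' @param replicon A [replicon_spec()]; defaults to [sim_replicon()].
#' @param n_reads Number of reads to draw.
#' @param read_len_bp Read length (default 50 bp, typical short-read
#'   sequencing).
#' @param pi_ter,pi_grad,pi_phage Mixture weights of peak, gradient and
#'   hotspot components.
#' @param peak_shape `"rectangular"`, `"triangular"` or `"laplace"`.
#' @param peak_width_bp Peak width in bp.
#' @param peak_center 1-based position (default the replicon's `dif_pos`).
#' @param peak_asymmetry Fraction of peak mass shifted to the right flank
#'   (0 = symmetric; capped at 1).
#' @param phage_interval A [genome_interval()] for the hotspot (required
#'   if `pi_phage > 0`).
#' @param seed Integer seed; simulation is a pure function of the params.
#' @return An object of class `simulation_params`.
#' @export
simulation_params <- function(replicon = sim_replicon(), n_reads = 200000,
                              read_len_bp = 50, pi_ter = 0,
                              peak_shape = c("rectangular", "triangular", "laplace"),
                              peak_width_bp = 6000,
                              peak_center = replicon$dif_pos,
                              peak_asymmetry = 0, pi_grad = 0, pi_phage = 0,
                              phage_interval = NULL, seed = 1L) {
  peak_shape <- match.arg(peak_shape)
  stopifnot(n_reads >= 0, read_len_bp >= 1, peak_width_bp >= 1,
            peak_asymmetry >= 0)
  if (pi_ter < 0 || pi_grad < 0 || pi_phage < 0 ||
      pi_ter + pi_grad + pi_phage > 1)
    abort("mixture weights must be non-negative and sum to at most 1",
          class = "terenrich_parameter_error")
  if (pi_ter > 0 && is.null(peak_center))
    abort("peak component needs a peak_center (or a replicon with dif_pos)",
          class = "terenrich_parameter_error")
  if (pi_grad > 0 && (is.null(replicon$ori_pos) || is.null(peak_center)))
    abort("gradient component needs ori_pos and peak_center",
          class = "terenrich_parameter_error")
  if (pi_phage > 0 && is.null(phage_interval))
    abort("phage component needs a phage_interval",
          class = "terenrich_parameter_error")
  structure(list(replicon = replicon, n_reads = as.integer(n_reads),
                 read_len_bp = as.integer(read_len_bp), pi_ter = pi_ter,
                 peak_shape = peak_shape, peak_width_bp = peak_width_bp,
                 peak_center = peak_center,
                 peak_asymmetry = min(peak_asymmetry, 1),
                 pi_grad = pi_grad, pi_phage = pi_phage,
                 phage_interval = phage_interval, seed = as.integer(seed)),
            class = "simulation_params")
}

#' A desk-scale simulated replicon
#'
#' A 1 Mb circular chromosome with the origin at position 1, *dif* at
#' 500,000 and a 6,001 bp *ter* window centred on it — the default world
#' for simulator presets and tests. Real replicon specifications can be
#' used in its place throughout.
#'
#' @param length_bp Replicon length (default 1e6).
#' @return A [replicon_spec()].
#' @export
sim_replicon <- function(length_bp = 1e6) {
  dif <- length_bp / 2
  replicon_spec("simulated 1 Mb chromosome", "SIM1M", length_bp,
                circular = TRUE, ter_start = dif - 3000, ter_end = dif + 3000,
                dif_pos = dif, ori_pos = 1)
}

# signed circular offset of positions 1..L from center, in (-L/2, L/2]
signed_offset <- function(pos, center, L) {
  d <- (pos - center) %% L
  ifelse(d > L / 2, d - L, d)
}

# density of |offset| for each kernel (integrates to 1 over [0, Inf))
kernel_abs_density <- function(d_abs, shape, width) {
  half <- width / 2
  switch(shape,
    rectangular = ifelse(d_abs <= half, 1 / half, 0),
    triangular = ifelse(d_abs <= half, 2 * (1 - d_abs / half) / half, 0),
    laplace = {
      b <- width / 8
      exp(-d_abs / b) / b
    })
}

# draw n absolute offsets from a kernel
kernel_draw_abs <- function(n, shape, width) {
  half <- width / 2
  switch(shape,
    rectangular = runif(n) * half,
    triangular = half * (1 - sqrt(runif(n))),
    laplace = rexp(n, rate = 8 / width))
}

# per-base probability of a read START at each position under the mixture
mixture_density <- function(params) {
  rp <- params$replicon
  L <- rp$length_bp
  dens <- base::rep((1 - params$pi_ter - params$pi_grad - params$pi_phage) / L, L)
  if (params$pi_ter > 0) {
    d <- signed_offset(seq_len(L), params$peak_center, L)
    pr <- min(1, 0.5 + params$peak_asymmetry / 2)
    f <- kernel_abs_density(abs(d), params$peak_shape, params$peak_width_bp)
    wt <- ifelse(d > 0, pr, ifelse(d < 0, 1 - pr, 0.5))
    k <- wt * f
    dens <- dens + params$pi_ter * k / sum(k)
  }
  if (params$pi_grad > 0) {
    pos <- seq_len(L)
    dcw <- (pos - rp$ori_pos) %% L            # clockwise distance from ori
    dccw <- (rp$ori_pos - pos) %% L           # counter-clockwise
    Dcw <- (params$peak_center - rp$ori_pos) %% L
    Dccw <- (rp$ori_pos - params$peak_center) %% L
    g <- pmax(0, 1 - dcw / Dcw) + pmax(0, 1 - dccw / Dccw)
    dens <- dens + params$pi_grad * g / sum(g)
  }
  if (params$pi_phage > 0) {
    iv <- params$phage_interval
    inside <- position_in_interval(seq_len(L), iv, rp)
    dens <- dens + params$pi_phage * as.numeric(inside) / sum(inside)
  }
  dens
}

#' Simulate a read-mapping set from a mixture of positional components
#'
#' Each read's start is drawn i.i.d. from the mixture described by
#' [simulation_params()]; the read interval is `(start, start +
#' read_len_bp - 1)` with origin wrap on circular replicons, and strands
#' are assigned 50/50. The result is a pure function of the parameters
#' (including the seed).
#'
#' @param params A [simulation_params()] object.
#' @return A [read_mappings()] tibble.
#' @export
simulate_reads <- function(params) {
  stopifnot(inherits(params, "simulation_params"))
  rp <- params$replicon
  L <- rp$length_bp
  n <- params$n_reads
  p <- c(bg = 1 - params$pi_ter - params$pi_grad - params$pi_phage,
         ter = params$pi_ter, grad = params$pi_grad, phage = params$pi_phage)
  withr::with_seed(params$seed, {
    comp <- sample.int(4L, n, replace = TRUE, prob = p)
    start <- numeric(n)
    i <- comp == 1L
    start[i] <- sample.int(L, sum(i), replace = TRUE)
    i <- comp == 2L
    if (any(i)) {
      m <- sum(i)
      pr <- min(1, 0.5 + params$peak_asymmetry / 2)
      side <- ifelse(runif(m) < pr, 1, -1)
      off <- kernel_draw_abs(m, params$peak_shape, params$peak_width_bp)
      start[i] <- wrap1(round(params$peak_center + side * off), L)
    }
    i <- comp == 3L
    if (any(i)) {
      m <- sum(i)
      Dcw <- (params$peak_center - rp$ori_pos) %% L
      Dccw <- (rp$ori_pos - params$peak_center) %% L
      cw <- runif(m) < Dcw / (Dcw + Dccw)   # replichore mass is prop. to length
      d <- numeric(m)
      d[cw] <- Dcw * (1 - sqrt(1 - runif(sum(cw))))
      d[!cw] <- Dccw * (1 - sqrt(1 - runif(sum(!cw))))
      start[i] <- wrap1(round(rp$ori_pos + ifelse(cw, 1, -1) * d), L)
    }
    i <- comp == 4L
    if (any(i)) {
      iv <- params$phage_interval
      len <- interval_length(iv, rp)
      start[i] <- wrap1(iv$start + floor(runif(sum(i)) * len), L)
    }
    strand <- sample(c("+", "-"), n, replace = TRUE)
    read_mappings(tibble(start = start,
                         end = start + params$read_len_bp - 1,
                         strand = strand), rp)
  })
}

#' Predicted pre-rounding enrichment for simulation parameters
#'
#' The analysis oracle: the expected ter-window read count divided by the
#' expected count of a typical (non-ter) null window. For a
#' background-plus-rectangular-peak mixture whose kernel lies entirely
#' inside ter this has the closed form
#' `1 + pi_ter * G / ((1 - pi_ter) * w)` with `G` the replicon length and
#' `w` the window width; any other mixture is integrated numerically from
#' the per-base mixture density.
#'
#' @param params A [simulation_params()] object.
#' @param window_bp Null window width (default: the ter window length).
#' @return The expected pre-rounding enrichment (real).
#' @export
expected_enrichment <- function(params, window_bp = NULL) {
  rp <- params$replicon
  ter <- ter_interval(rp)
  w <- window_bp %||% interval_length(ter, rp)
  G <- rp$length_bp
  closed <- params$pi_grad == 0 && params$pi_phage == 0 &&
    params$peak_shape == "rectangular" &&
    !is.null(params$peak_center) &&
    position_in_interval(wrap1(params$peak_center - params$peak_width_bp / 2, G), ter, rp) &&
    position_in_interval(wrap1(params$peak_center + params$peak_width_bp / 2, G), ter, rp)
  if (params$pi_ter == 0 && params$pi_grad == 0 && params$pi_phage == 0)
    return(1)
  if (closed)
    return(1 + params$pi_ter * G / ((1 - params$pi_ter) * w))
  dens <- mixture_density(params)
  ter_mass <- sum(dens[which(position_in_interval(seq_len(G), ter, rp))])
  L_out <- G - interval_length(ter, rp)
  arc <- wrap1(ter$end + seq_len(L_out), G)
  da <- dens[arc]
  cs <- c(0, cumsum(da))
  n_win <- L_out - w + 1
  win_mass <- cs[(w + 1):(L_out + 1)] - cs[1:n_win]
  ter_mass / mean(win_mass)
}

#' Simulation parameters targeting a given pre-rounding enrichment
#'
#' Inverts the closed-form enrichment prediction for a rectangular peak
#' fully inside ter: `pi_ter = (E - 1) w / (G + (E - 1) w)`.
#'
#' @param target Desired pre-rounding enrichment (>= 1).
#' @param replicon A [replicon_spec()] with a dif-centred ter window.
#' @param n_reads,seed Passed to [simulation_params()].
#' @return A [simulation_params()] object.
#' @export
enrichment_target_params <- function(target, replicon = sim_replicon(),
                                     n_reads = 200000, seed = 1L) {
  stopifnot(target >= 1)
  w <- interval_length(ter_interval(replicon), replicon)
  G <- replicon$length_bp
  pi_ter <- (target - 1) * w / (G + (target - 1) * w)
  simulation_params(replicon, n_reads = n_reads, pi_ter = pi_ter,
                    peak_shape = "rectangular",
                    peak_width_bp = w - 1,  # keep the kernel inside ter
                    seed = seed)
}

#' Named simulator presets for the observed coverage-profile classes
#'
#' Fully specified, seeded parameter sets mirroring the coverage-profile
#' classes seen in vesicle DNA: `wt_ecoli` (narrow dif-centred peak,
#' pre-rounding enrichment 14), `xer_mutant` (3.5x broader, asymmetric,
#' lower-centre peak — the recombinase-knockout signature),
#' `pmarinus` (broad 100 kb Laplace peak over sparse background),
#' `paeruginosa_lysis` (dominant ori-to-ter replication gradient from
#' lysed replicating cells), `vcholerae_phage` (moderate dif peak plus a
#' phage hotspot), and `uniform` (no positional structure).
#'
#' @param name Preset name.
#' @return A [simulation_params()] object.
#' @export
scenario_preset <- function(name = c("wt_ecoli", "xer_mutant", "pmarinus",
                                     "paeruginosa_lysis", "vcholerae_phage",
                                     "uniform")) {
  name <- match.arg(name)
  rp <- sim_replicon()
  w <- interval_length(ter_interval(rp), rp)
  G <- rp$length_bp
  pi_for <- function(E) (E - 1) * w / (G + (E - 1) * w)
  switch(name,
    uniform = simulation_params(rp, n_reads = 100000, seed = 101L),
    wt_ecoli = simulation_params(rp, n_reads = 200000, pi_ter = pi_for(14),
                                 peak_shape = "rectangular",
                                 peak_width_bp = 6000, seed = 202L),
    xer_mutant = simulation_params(rp, n_reads = 200000, pi_ter = 0.0582,
                                   peak_shape = "rectangular",
                                   peak_width_bp = 21000,
                                   peak_asymmetry = 0.3, seed = 203L),
    pmarinus = simulation_params(rp, n_reads = 200000, pi_ter = 0.6,
                                 peak_shape = "laplace",
                                 peak_width_bp = 100000, seed = 204L),
    paeruginosa_lysis = simulation_params(rp, n_reads = 200000, pi_ter = 0.02,
                                          peak_shape = "laplace",
                                          peak_width_bp = 20000,
                                          pi_grad = 0.75, seed = 205L),
    vcholerae_phage = simulation_params(rp, n_reads = 200000,
                                        pi_ter = pi_for(9),
                                        peak_shape = "rectangular",
                                        peak_width_bp = 6000,
                                        pi_phage = 0.15,
                                        phage_interval = genome_interval(700001, 715000),
                                        seed = 206L))
}
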