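#' Secondary chemical shift
#'
#' `Ddelta = delta_obs - delta_rc - correction`: observed shift minus the
#' random-coil reference, minus an optional isotope correction (nonzero for
#' perdeuterated samples; 0 for protonated ones). Positive Calpha/CO values
#' indicate helical, negative extended (beta) structure; values near zero
#' are coil-like.
#'
#' @param delta_obs observed shift, ppm (vectorised)
#' @param delta_rc random-coil reference shift, ppm
#' @param correction deuterium isotope correction, ppm (default 0)
#' @return secondary shift, ppm
#' @export
#' @examples
#' secondary_shift(58.0, 56.0, 0.5)   # 1.5
secondary_shift <- function(delta_obs, delta_rc, correction = 0) {
  if (any(!is.finite(delta_obs)) || any(!is.finite(delta_rc))) {
    stop("shifts must be finite; missing reference values are an error")
  }
  delta_obs - delta_rc - correction
}

#' Secondary shifts for a table of observations
#'
#' Joins an observed-shift table to a random-coil reference by residue type
#' and atom, and returns per-record secondary shifts. Any observation whose
#' residue type/atom pair is absent from the reference is a hard error
#' naming the offending residue.
#'
#' @param obs data.frame with columns `residue` (number), `type`
#'   (one-letter), `atom` (`"CA"`, `"CO"`, ...), `delta_obs` (ppm)
#' @param reference data.frame with columns `type`, `atom`, `delta_rc`
#'   (e.g. from [read_random_coil_table()])
#' @param correction scalar or per-row isotope correction, ppm
#' @return `obs` with an added `sec_shift` column
#' @export
secondary_shift_table <- function(obs, reference, correction = 0) {
  key_o <- paste(obs$type, obs$atom)
  key_r <- paste(reference$type, reference$atom)
  idx <- match(key_o, key_r)
  if (anyNA(idx)) {
    miss <- unique(key_o[is.na(idx)])
    stop("no random-coil reference for: ", paste(miss, collapse = ", "))
  }
  obs$sec_shift <- secondary_shift(obs$delta_obs, reference$delta_rc[idx],
                                   correction)
  obs
}

# centered rolling mean with shrinking windows at the edges
.roll_mean <- function(v, window) {
  h <- (window - 1) / 2
  n <- length(v)
  vapply(seq_len(n), function(i) {
    mean(v[max(1, i - h):min(n, i + h)], na.rm = TRUE)
  }, numeric(1))
}

#' Per-residue structural propensity from secondary shifts
#'
#' Sliding-window average of the Calpha and CO secondary shifts; a residue
#' is called `helix` when both averages exceed `+t`, `extended` when both
#' fall below `-t`, and `coil` otherwise. Thresholds default to
#' conventional values (0.7 ppm Calpha, 0.5 ppm CO) with a 3-residue
#' window.
#'
#' @param d_ca,d_co secondary shifts, ppm, aligned on `residues`
#' @param residues residue numbers (any consistent numbering)
#' @param window odd sliding-window width, residues (default 3)
#' @param t_ca,t_co call thresholds, ppm
#' @return data.frame with `residue`, smoothed `d_ca`/`d_co`, and `call`
#'   (factor: helix/extended/coil)
#' @export
propensity_call <- function(d_ca, d_co, residues = seq_along(d_ca),
                            window = 3, t_ca = 0.7, t_co = 0.5) {
  n <- length(d_ca)
  if (length(d_co) != n || length(residues) != n) {
    stop("d_ca, d_co and residues must be aligned")
  }
  if (window %% 2 != 1) stop("window must be odd")
  if (window > n) stop("window larger than the series")
  ca_s <- .roll_mean(d_ca, window)
  co_s <- .roll_mean(d_co, window)
  call <- ifelse(ca_s > t_ca & co_s > t_co, "helix",
                 ifelse(ca_s < -t_ca & co_s < -t_co, "extended", "coil"))
  data.frame(residue = residues, d_ca = ca_s, d_co = co_s,
             call = factor(call, levels = c("helix", "extended", "coil")))
}

#' Flag hydrogen bonds weakened (or strengthened) in low-stability domains
#'
#' For each structurally equivalent H-bond group, compares the
#' through-H-bond scalar coupling magnitudes `|h3J_NC'|` of the
#' reduced-stability domains against the stable domains. A group is flagged
#' `weaker` when at least `k_min` reduced-stability domains with data have a
#' coupling below the minimum over the stable domains with data in that
#' group; `stronger` by the mirrored rule against the stable maximum (the
#' strict, order-invariant reading). If both rules fire (possible only with
#' four or more reduced-stability measurements) the destabilization call
#' `weaker` wins. Missing values are excluded from the comparisons and
#' counted in the output; groups with no stable-domain data are flagged
#' `none` with a warning.
#'
#' @param records data.frame with columns `group` (integer id aligning
#'   equivalent H-bonds across domains), `domain`, `abs_J` (Hz, NA when not
#'   measurable) and optionally `sheet`
#' @param stable_domains,reduced_domains character vectors of domain ids
#' @param k_min minimum number of reduced-stability domains required
#'   (default 2)
#' @return data.frame, one row per group: `group`, `flag`
#'   (weaker/stronger/none), `n_stable`, `n_reduced`, `n_below`, `n_above`,
#'   `stable_min`, `stable_max`
#' @export
flag_weakened_hbonds <- function(records, stable_domains, reduced_domains,
                                 k_min = 2) {
  need <- c("group", "domain", "abs_J")
  if (!all(need %in% names(records))) {
    stop("records needs columns: ", paste(need, collapse = ", "))
  }
  if (any(records$abs_J < 0, na.rm = TRUE)) stop("abs_J must be >= 0")
  groups <- sort(unique(records$group))
  out <- lapply(groups, function(g) {
    rg <- records[records$group == g, , drop = FALSE]
    # duplicated identical records must not change the outcome
    rg <- unique(rg[c("group", "domain", "abs_J")])
    st <- rg$abs_J[rg$domain %in% stable_domains]
    rd <- rg$abs_J[rg$domain %in% reduced_domains]
    st <- st[!is.na(st)]; rd <- rd[!is.na(rd)]
    if (!length(st)) {
      warning(sprintf("group %s has no stable-domain data", g))
      return(data.frame(group = g, flag = "none", n_stable = 0L,
                        n_reduced = length(rd), n_below = NA_integer_,
                        n_above = NA_integer_, stable_min = NA_real_,
                        stable_max = NA_real_))
    }
    n_below <- sum(rd < min(st))
    n_above <- sum(rd > max(st))
    flag <- if (n_below >= k_min) "weaker"
            else if (n_above >= k_min) "stronger"
            else "none"
    data.frame(group = g, flag = flag, n_stable = length(st),
               n_reduced = length(rd), n_below = n_below,
               n_above = n_above, stable_min = min(st),
               stable_max = max(st))
  })
  res <- do.call(rbind, out)
  res$flag <- factor(res$flag, levels = c("weaker", "stronger", "none"))
  res
}

#' Read the packaged H-bond coupling table
#'
#' Per-domain `|h3J_NC'|` magnitudes for the 24 structurally equivalent
#' backbone H-bond positions of the KOW beta-barrel, with the reason a value
#' is missing (peak overlap, no HNCO peak, no equivalent H-bond, ...)
#' preserved in the `note` column.
#'
#' @param path TSV path; defaults to the packaged table
#' @return data.frame with columns `group`, `sheet`, `domain`, `donor`,
#'   `acceptor`, `abs_J`, `sigma_J`, `note`
#' @export
read_hbond_table <- function(path = system.file("extdata",
                                                "hbond_couplings_kow.tsv",
                                                package = "kowtherm")) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  df$abs_J <- as.numeric(df$abs_J)
  df$sigma_J <- as.numeric(df$sigma_J)
  df
}

#' Read a random-coil chemical-shift reference table
#'
#' The packaged default carries commonly used Calpha and CO random-coil
#' values for the 20 standard residues; it is an editable starting point,
#' not a frozen standard — replace it with your preferred reference (e.g. a
#' sequence-corrected prediction) for quantitative work.
#'
#' @param path TSV path; defaults to the packaged table
#' @return data.frame with columns `type`, `atom`, `delta_rc`
#' @export
read_random_coil_table <- function(path = system.file("extdata",
                                                      "random_coil_shifts.tsv",
                                                      package = "kowtherm")) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}
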