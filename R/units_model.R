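#' Volume context for concentration/molecule conversions
#'
#' Bundles the system volume and Avogadro's constant. In a well-mixed volume
#' `V` a concentration `c` (in micromolar) corresponds to
#' `c * 1e-6 * V * N_A` molecules; zeroth- and second-order macroscopic rate
#' constants are scaled by the same factor when moving to the stochastic
#' (molecule-count) regime, first-order rates are unchanged.
#'
#' @param volume System volume in liters. Default 1 femtoliter (1e-15 L),
#'   the scale of a bacterial cell.
#' @param avogadro Avogadro's constant in molecules per mole.
#' @return An object of class `volume_context`.
#' @examples
#' ctx <- volume_context()
#' to_molecules(0.1, ctx) # 60
#' @export
volume_context <- function(volume = 1e-15, avogadro = 6.02214179e23) {
  if (!is.numeric(volume) || length(volume) != 1L || volume <= 0)
    stop("`volume` must be a single positive number (liters)")
  if (!is.numeric(avogadro) || avogadro <= 0)
    stop("`avogadro` must be positive")
  structure(list(volume = volume, avogadro = avogadro),
            class = "volume_context")
}

#' @export
print.volume_context <- function(x, ...) {
  cat(sprintf("<volume_context> V = %g L, 1 uM = %.4g molecules\n",
              x$volume, molecules_per_um(x)))
  invisible(x)
}

# molecules per 1 uM of concentration: V * N_A * 1e-6
molecules_per_um <- function(ctx) ctx$volume * ctx$avogadro * 1e-6

#' Convert a concentration to a molecule count
#'
#' @param conc Concentration(s) in micromolar; must be non-negative.
#' @param ctx A [volume_context()].
#' @return Integer molecule count(s), rounded to the nearest integer.
#' @examples
#' ctx <- volume_context()
#' to_molecules(c(0.1, 0.01), ctx) # 60 6
#' @export
to_molecules <- function(conc, ctx = volume_context()) {
  stopifnot(inherits(ctx, "volume_context"))
  if (any(conc < 0)) stop("negative concentration")
  stats::setNames(as.integer(round(conc * molecules_per_um(ctx))),
                  names(conc))
}

#' Convert a molecule count to a concentration in micromolar
#'
#' Inverse of [to_molecules()] up to one-molecule quantization.
#'
#' @param count Molecule count(s); must be non-negative.
#' @param ctx A [volume_context()].
#' @return Concentration(s) in micromolar.
#' @export
to_concentration <- function(count, ctx = volume_context()) {
  stopifnot(inherits(ctx, "volume_context"))
  if (any(count < 0)) stop("negative molecule count")
  count / molecules_per_um(ctx)
}

#' Rate constants of the linear two-state protein model
#'
#' The motif interconverts a protein between an unmodified state P and a
#' modified state Pm. Macroscopic units: `ks` uM/time (synthesis of P),
#' `ka` 1/(uM time) (signal-coupled P -> Pm conversion), `kf`, `kr` 1/time
#' (basal forward/reverse conversion), `dP`, `dPm` 1/time (degradation).
#' The defaults are the study parameterization; `dP = 0` gives perfect
#' adaptation, `dP = 0.01` near-perfect adaptation.
#'
#' @param ks,ka,kf,kr,dP,dPm Non-negative rate constants.
#' @return An object of class `rate_set`.
#' @examples
#' two_state_rates()            # near-perfect adaptation defaults
#' two_state_rates(dP = 0)      # perfect adaptation
#' @export
two_state_rates <- function(ks = 0.01, ka = 1, kf = 1, kr = 10, dP = 0.01,
                            dPm = 1) {
  r <- c(ks = ks, ka = ka, kf = kf, kr = kr, dP = dP, dPm = dPm)
  if (any(!is.finite(r)) || any(r < 0)) stop("all rates must be finite and >= 0")
  structure(as.list(r), class = "rate_set")
}

#' @export
print.rate_set <- function(x, ...) {
  cat("<rate_set> ", paste(names(x), unlist(x), sep = " = ", collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' Rate constants of the kinase/phosphatase-mediated two-state model
#'
#' Extension in which transitions between P and Pm are mediated by a kinase
#' (A_kin) and a phosphatase (B_phos) through reversible enzyme-substrate
#' complexes AP and BPm. `ka1`/`kd1` are association rates (1/(uM time)),
#' `ka2`/`kd2` complex unbinding and `ka3`/`kd3` catalytic conversion
#' (1/time). Defaults are the mediated-model parameterization of the study.
#'
#' @param ks,kf,kr,dP,dPm As in [two_state_rates()].
#' @param ka1,ka2,ka3 Kinase binding / unbinding / catalysis rates.
#' @param kd1,kd2,kd3 Phosphatase binding / unbinding / catalysis rates.
#' @return An object of class `mediator_rate_set` (also a `rate_set`).
#' @export
mediator_rates <- function(ks = 0.05, kf = 1, kr = 0.1, dP = 0.01, dPm = 10,
                           ka1 = 1e3, ka2 = 10, ka3 = 10, kd1 = 10, kd2 = 10,
                           kd3 = 10) {
  r <- c(ks = ks, kf = kf, kr = kr, dP = dP, dPm = dPm, ka1 = ka1, ka2 = ka2,
         ka3 = ka3, kd1 = kd1, kd2 = kd2, kd3 = kd3)
  if (any(!is.finite(r)) || any(r < 0)) stop("all rates must be finite and >= 0")
  structure(as.list(r), class = c("mediator_rate_set", "rate_set"))
}

new_reaction_network <- function(species, stoich, reactants, rates,
                                 rate_names, signal) {
  stopifnot(nrow(stoich) == length(species), all(dim(stoich) == dim(reactants)),
            ncol(stoich) == length(rates))
  if (any(colSums(abs(stoich)) == 0)) stop("a reaction has a zero change vector")
  storage.mode(stoich) <- "integer"
  storage.mode(reactants) <- "integer"
  dimnames(stoich) <- dimnames(reactants) <- list(species, rate_names)
  structure(list(species = species, stoich = stoich, reactants = reactants,
                 rates = stats::setNames(rates, rate_names),
                 rate_names = rate_names, signal = signal),
            class = "reaction_network")
}

#' @export
print.reaction_network <- function(x, ...) {
  cat(sprintf("<reaction_network> %d species (%s), %d reactions\n",
              length(x$species), paste(x$species, collapse = ", "),
              ncol(x$stoich)))
  if (x$signal$mode == "rate")
    cat("  signal multiplies rate(s):",
        paste(x$rate_names[x$signal$reactions], collapse = ", "), "\n")
  else
    cat("  signal sets copy number of species:", x$signal$species, "\n")
  invisible(x)
}

#' Reaction network of the linear two-state model
#'
#' Six elementary reactions over species (P, Pm): synthesis 0 -> P (`ks`),
#' basal conversion P -> Pm (`kf`), signal-coupled conversion P -> Pm with
#' propensity `ka * A(t) * n_P` (the external signal A is not a species; it
#' enters as a time-varying first-order rate), reverse conversion Pm -> P
#' (`kr`), and degradations P -> 0 (`dP`), Pm -> 0 (`dPm`).
#'
#' @param rates A [two_state_rates()] object.
#' @return A `reaction_network`.
#' @export
two_state_network <- function(rates = two_state_rates()) {
  stopifnot(inherits(rates, "rate_set"), !inherits(rates, "mediator_rate_set"))
  species <- c("P", "Pm")
  rate_names <- c("ks", "kf", "ka", "kr", "dP", "dPm")
  #            ks  kf  ka  kr  dP dPm
  stoich <- matrix(c(1, -1, -1,  1, -1,  0,
                     0,  1,  1, -1,  0, -1),
                   nrow = 2, byrow = TRUE)
  reactants <- matrix(c(0, 1, 1, 0, 1, 0,
                        0, 0, 0, 1, 0, 1),
                      nrow = 2, byrow = TRUE)
  new_reaction_network(species, stoich, reactants,
                       unlist(rates[rate_names]), rate_names,
                       signal = list(mode = "rate", reactions = 3L))
}

#' Reaction network of the kinase/phosphatase-mediated model
#'
#' Eleven reactions over species (P, Pm, A_kin, B_phos, AP, BPm): the five
#' signal-independent reactions of the linear model (`ks`, `kf`, `kr`, `dP`,
#' `dPm`) plus kinase binding A_kin + P -> AP (`ka1`), unbinding
#' AP -> A_kin + P (`ka2`), catalysis AP -> A_kin + Pm (`ka3`) and the
#' symmetric phosphatase reactions on Pm (`kd1`, `kd2`, `kd3`). The input
#' signal is a molecular species here: signal steps SET the unbound copy
#' number of `signal_species` (default the kinase), leaving complexes
#' untouched.
#'
#' @param rates A [mediator_rates()] object.
#' @param signal_species Which species the input signal sets, `"A_kin"` or
#'   `"B_phos"`.
#' @return A `reaction_network`.
#' @export
mediator_network <- function(rates = mediator_rates(),
                             signal_species = c("A_kin", "B_phos")) {
  stopifnot(inherits(rates, "mediator_rate_set"))
  signal_species <- match.arg(signal_species)
  species <- c("P", "Pm", "A_kin", "B_phos", "AP", "BPm")
  rate_names <- c("ks", "kf", "kr", "dP", "dPm",
                  "ka1", "ka2", "ka3", "kd1", "kd2", "kd3")
  rx <- function(...) {
    v <- numeric(6); names(v) <- species
    args <- list(...)
    v[names(args)] <- unlist(args)
    v
  }
  stoich <- cbind(
    ks  = rx(P = 1),
    kf  = rx(P = -1, Pm = 1),
    kr  = rx(Pm = -1, P = 1),
    dP  = rx(P = -1),
    dPm = rx(Pm = -1),
    ka1 = rx(A_kin = -1, P = -1, AP = 1),
    ka2 = rx(AP = -1, A_kin = 1, P = 1),
    ka3 = rx(AP = -1, A_kin = 1, Pm = 1),
    kd1 = rx(B_phos = -1, Pm = -1, BPm = 1),
    kd2 = rx(BPm = -1, B_phos = 1, Pm = 1),
    kd3 = rx(BPm = -1, B_phos = 1, P = 1))
  reactants <- cbind(
    ks  = rx(),
    kf  = rx(P = 1),
    kr  = rx(Pm = 1),
    dP  = rx(P = 1),
    dPm = rx(Pm = 1),
    ka1 = rx(A_kin = 1, P = 1),
    ka2 = rx(AP = 1),
    ka3 = rx(AP = 1),
    kd1 = rx(B_phos = 1, Pm = 1),
    kd2 = rx(BPm = 1),
    kd3 = rx(BPm = 1))
  new_reaction_network(species, stoich, reactants,
                       unlist(rates[rate_names]), rate_names,
                       signal = list(mode = "species",
                                     species = signal_species))
}

#' Molecule-unit (stochastic) rate constants of a network
#'
#' Converts the macroscopic rates of a network to the molecule-count regime:
#' zeroth-order rates are multiplied by `V * N_A * 1e-6`, second-order rates
#' divided by it, first-order rates unchanged. The signal-coupled channel of
#' the linear model keeps its macroscopic value because the signal stays in
#' micromolar (`ka * A` is a first-order rate on P).
#'
#' @param network A `reaction_network`.
#' @param ctx A [volume_context()].
#' @return Named numeric vector of per-reaction stochastic rate constants.
#' @export
molecule_rates <- function(network, ctx = volume_context()) {
  om <- molecules_per_um(ctx)
  order <- colSums(network$reactants)
  network$rates * om^(1 - order)
}

# signal metadata in the form the compiled cores expect
signal_core_args <- function(network, signal, ctx) {
  lev <- signal$level
  if (network$signal$mode == "rate") {
    scaled <- seq_along(network$rate_names) %in% network$signal$reactions
    list(sig_scaled = scaled, sig_species = -1L,
         sig_t = signal$t_start, sig_level = lev,
         sig_level_mol = integer(length(lev)))
  } else {
    idx <- match(network$signal$species, network$species)
    list(sig_scaled = rep(FALSE, length(network$rate_names)),
         sig_species = idx - 1L, sig_t = signal$t_start, sig_level = lev,
         sig_level_mol = to_molecules(lev, ctx))
  }
}
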