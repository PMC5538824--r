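# Equilibrium speciation of calibration solutions containing Ca2+, Mg2+ and
# the chelators EGTA and fura-2, at fixed (buffered) pH.
#
# Stability and protonation constants are stored as log10 association
# constants at a reference ionic strength and temperature and corrected to
# the working conditions with the Davies equation and the van't Hoff
# relation. pH is read as hydrogen-ion *activity* (what a glass electrode
# reports); the free H+ concentration entering the mass-action terms is
# recovered through the Davies single-ion activity coefficient.

# Critical-compilation style constants (log10 association, molar units) at
# I = 0.1 M and 20 degrees C. Enthalpies in kJ/mol drive the van't Hoff
# temperature correction; fura-2 enthalpies are not well characterised and
# are taken as zero (the package is used within a few degrees of reference).
.CHELATORS <- list(
  "EGTA" = list(
    z_ligand = -4L,
    logK = c(H1 = 9.47, H2 = 8.85, Ca = 10.97, Mg = 5.21),
    dH_kJ = c(H1 = -23.4, H2 = -17.8, Ca = -33.1, Mg = 21.3),
    I_ref = 0.1, T_ref = 20
  ),
  "fura-2" = list(
    z_ligand = -5L,
    logK = c(H1 = 6.40, H2 = 5.00, Ca = 6.85, Mg = 2.00),
    dH_kJ = c(H1 = 0, H2 = 0, Ca = 0, Mg = 0),
    I_ref = 0.1, T_ref = 20
  )
)

#' Table of chelator stability constants used by the speciation solver
#'
#' Returns the shipped set of log10 association constants (protonation and
#' Ca/Mg stability) for the supported chelators, together with the reference
#' ionic strength and temperature they refer to and the reaction enthalpies
#' used for temperature correction.
#'
#' @return A data frame with one row per (ligand, reaction) pair.
#' @export
chelator_constants <- function() {
  do.call(rbind, lapply(names(.CHELATORS), function(nm) {
    ch <- .CHELATORS[[nm]]
    data.frame(
      ligand = nm,
      reaction = names(ch$logK),
      logK = unname(ch$logK),
      dH_kJ_mol = unname(ch$dH_kJ),
      I_ref_M = ch$I_ref,
      T_ref_C = ch$T_ref,
      z_ligand = ch$z_ligand,
      stringsAsFactors = FALSE
    )
  }))
}

# Davies activity function f(I) with A fixed at its ~25 C value; log10
# gamma_i = -z_i^2 f(I).
.davies_f <- function(I, A = 0.51) A * (sqrt(I) / (1 + sqrt(I)) - 0.3 * I)

# Correct a log10 association constant from (I_ref, T_ref) to (I, T).
# d_z2 = z(product)^2 - sum z(reactants)^2 for the association reaction.
.adjust_logK <- function(logK_ref, d_z2, I, I_ref, dH_kJ, temp_C, T_ref_C) {
  lk <- logK_ref + d_z2 * (.davies_f(I) - .davies_f(I_ref))
  if (dH_kJ != 0) {
    R <- 8.31446e-3 # kJ/(mol K)
    T1 <- T_ref_C + 273.15
    T2 <- temp_C + 273.15
    lk <- lk - dH_kJ / (log(10) * R) * (1 / T2 - 1 / T1)
  }
  lk
}

# All working association constants and the proton activity coefficient for
# one chelator at the given conditions.
.chelator_at <- function(chelator, ionic_strength, temp_C) {
  ch <- .CHELATORS[[chelator]]
  if (is.null(ch)) {
    stop(structure(class = c("cabuffer_unsupported_ligand", "error", "condition"),
                   list(message = sprintf("unsupported ligand '%s'; supported: %s",
                                          chelator,
                                          paste(names(.CHELATORS), collapse = ", ")),
                        call = sys.call(-1))))
  }
  zL <- ch$z_ligand
  d_z2 <- c(
    H1 = (zL + 1)^2 - 1 - zL^2,          # H + L -> HL
    H2 = (zL + 2)^2 - 1 - (zL + 1)^2,    # H + HL -> H2L
    Ca = (zL + 2)^2 - 4 - zL^2,          # Ca + L -> CaL
    Mg = (zL + 2)^2 - 4 - zL^2           # Mg + L -> MgL
  )
  logK <- vapply(names(ch$logK), function(r) {
    .adjust_logK(ch$logK[[r]], d_z2[[r]], ionic_strength, ch$I_ref,
                 ch$dH_kJ[[r]], temp_C, ch$T_ref)
  }, numeric(1))
  list(logK = logK, z_ligand = zL)
}

# Free [H+] (M) from electrode pH at ionic strength I (activity convention).
.free_H <- function(pH, ionic_strength) {
  gamma_H <- 10^(-.davies_f(ionic_strength))
  10^(-pH) / gamma_H
}

#' Apparent (pH-corrected) dissociation constant of a chelator for Ca2+
#'
#' The apparent K_d folds competing protonation into the Ca2+ affinity:
#' K_d,app = alpha_H / K_Ca with alpha_H = 1 + [H]/K_H1 + [H]^2/(K_H1 K_H2),
#' all constants corrected to the stated temperature and ionic strength.
#' It decreases strictly with pH.
#'
#' @param chelator "EGTA" or "fura-2".
#' @param pH Solution pH (electrode reading), in [5, 10].
#' @param temperature_C Temperature in degrees C.
#' @param ionic_strength Ionic strength in M.
#' @return Apparent dissociation constant in micromolar.
#' @examples
#' apparent_kd("EGTA", pH = 7.2, temperature_C = 22, ionic_strength = 0.15)
#' @export
apparent_kd <- function(chelator, pH, temperature_C = 22, ionic_strength = 0.15) {
  .assert(is.numeric(pH) && is.finite(pH) && pH >= 5 && pH <= 10,
          "pH must be a finite value in [5, 10]")
  .assert(ionic_strength > 0, "ionic strength must be positive")
  ch <- .chelator_at(chelator, ionic_strength, temperature_C)
  H <- .free_H(pH, ionic_strength)
  KH1 <- 10^ch$logK[["H1"]]
  KH2 <- 10^ch$logK[["H2"]]
  alpha_H <- 1 + KH1 * H + KH1 * KH2 * H^2
  kd_M <- alpha_H / 10^ch$logK[["Ca"]]
  kd_M * 1e6
}

# Compound dissociation table: ion charges and counts for ionic-strength
# bookkeeping plus the element/ligand each compound delivers. HEPES is a
# zwitterion and K5 counter-ions of the fura salt are negligible at 50 uM:
# both are treated as inert for ionic strength.
.COMPOUNDS <- list(
  KCl    = list(ions = c("K" = 1, "Cl" = 1)),
  KOH    = list(ions = c("K" = 1)),
  NaCl   = list(ions = c("Na" = 1, "Cl" = 1)),
  NaOH   = list(ions = c("Na" = 1)),
  HCl    = list(ions = c("Cl" = 1)),
  MgCl2  = list(ions = c("Mg" = 1, "Cl" = 2), element = "Mg"),
  CaCl2  = list(ions = c("Ca" = 1, "Cl" = 2), element = "Ca"),
  HEPES  = list(ions = c()),
  EGTA   = list(ions = c(), chelator = "EGTA"),
  "fura-2" = list(ions = c(), chelator = "fura-2")
)
.ION_Z <- c(K = 1, Na = 1, Cl = -1, Ca = 2, Mg = 2)

#' Construct a calibration-solution composition
#'
#' @param compounds Named numeric vector or list of total concentrations in
#'   mM, e.g. `c(KCl = 129.5, EGTA = 4, CaCl2 = 2.7)`. Recognised names:
#'   KCl, KOH, NaCl, NaOH, HCl, MgCl2, CaCl2, HEPES, EGTA, "fura-2".
#' @param pH Buffered pH of the solution (held fixed; no proton balance is
#'   solved).
#' @param temperature_C Temperature in degrees C.
#' @param ionic_strength Ionic strength in M, or `NULL` to estimate it from
#'   the fully dissociated strong electrolytes plus the chelate anions
#'   (counted at charge 2-, the dominant complexed/protonated forms).
#' @return An object of class `solution_composition`.
#' @export
solution_composition <- function(compounds, pH, temperature_C = 22,
                                 ionic_strength = NULL) {
  compounds <- unlist(compounds)
  .assert(length(compounds) > 0 && !is.null(names(compounds)),
          "compounds must be a named vector of concentrations in mM")
  unknown <- setdiff(names(compounds), names(.COMPOUNDS))
  .assert(length(unknown) == 0,
          paste0("unknown compound(s): ", paste(unknown, collapse = ", ")))
  .assert(all(is.finite(compounds)) && all(compounds >= 0),
          "all total concentrations must be finite and non-negative")
  .assert(is.numeric(pH) && is.finite(pH) && pH >= 0 && pH <= 14,
          "pH must be finite and in [0, 14]")

  if (is.null(ionic_strength)) {
    I <- 0
    for (nm in names(compounds)) {
      ions <- .COMPOUNDS[[nm]]$ions
      for (ion in names(ions)) {
        I <- I + compounds[[nm]] * 1e-3 * ions[[ion]] * .ION_Z[[ion]]^2
      }
      if (!is.null(.COMPOUNDS[[nm]]$chelator)) {
        I <- I + compounds[[nm]] * 1e-3 * 4 # chelate anions as z = -2
      }
    }
    ionic_strength <- I / 2
  }
  structure(list(compounds = compounds, pH = pH,
                 temperature_C = temperature_C,
                 ionic_strength = ionic_strength),
            class = "solution_composition")
}

#' Read a solution recipe from a YAML file
#'
#' Expected layout: `compounds: {EGTA: 4.0, CaCl2: 2.7, ...}`, `pH: 7.2`,
#' optionally `temperature_C` and `ionic_strength`.
#'
#' @param path Path to the YAML recipe.
#' @return A `solution_composition`.
#' @export
read_solution_recipe <- function(path) {
  rec <- yaml::read_yaml(path)
  .assert(!is.null(rec$compounds) && !is.null(rec$pH),
          "recipe must contain 'compounds' and 'pH'")
  solution_composition(
    compounds = unlist(rec$compounds),
    pH = rec$pH,
    temperature_C = if (is.null(rec$temperature_C)) 22 else rec$temperature_C,
    ionic_strength = rec$ionic_strength
  )
}

#' Solve the free-ion equilibrium of a calibration solution
#'
#' Solves the coupled mass-action / mass-balance system for free Ca2+ and
#' Mg2+ in the presence of the recognised chelators at fixed pH. The solver
#' uses nested monotone root bracketing on the log-concentration scale,
#' followed by Newton polishing, and verifies element mass balance to
#' 1e-9 relative.
#'
#' @param solution A `solution_composition`.
#' @param purity Chelator purity as a fraction in (0, 1]; applied
#'   multiplicatively to all chelator totals (commercial EGTA is commonly a
#'   few percent short of nominal).
#' @return An object of class `speciation_result` with free Ca2+ (uM), free
#'   Mg2+ (mM), per-chelator species concentrations (mM) and apparent K_d
#'   values (uM).
#' @examples
#' r_def <- solution_composition(
#'   c(KCl = 129.5, KOH = 13, NaCl = 10.3, NaOH = 4.7, MgCl2 = 1,
#'     HEPES = 5, EGTA = 4, CaCl2 = 2.7, "fura-2" = 0.05), pH = 7.2)
#' solve_free_ca(r_def)
#' @export
solve_free_ca <- function(solution, purity = 1.0) {
  .assert(inherits(solution, "solution_composition"),
          "solution must be a solution_composition")
  .assert(is.numeric(purity) && purity > 0 && purity <= 1,
          "purity must be a fraction in (0, 1]")

  comp <- solution$compounds
  I <- solution$ionic_strength
  tC <- solution$temperature_C
  H <- .free_H(solution$pH, I)

  ca_T <- mg_T <- 0
  chel <- list() # name -> list(total_M, K (working constants), alpha_H)
  for (nm in names(comp)) {
    info <- .COMPOUNDS[[nm]]
    if (!is.null(info$element)) {
      if (info$element == "Ca") ca_T <- ca_T + comp[[nm]] * 1e-3
      if (info$element == "Mg") mg_T <- mg_T + comp[[nm]] * 1e-3
    }
    if (!is.null(info$chelator)) {
      ch <- .chelator_at(info$chelator, I, tC)
      KH1 <- 10^ch$logK[["H1"]]; KH2 <- 10^ch$logK[["H2"]]
      chel[[info$chelator]] <- list(
        total_M = comp[[nm]] * 1e-3 * purity,
        K_Ca = 10^ch$logK[["Ca"]],
        K_Mg = 10^ch$logK[["Mg"]],
        alpha_H = 1 + KH1 * H + KH1 * KH2 * H^2
      )
    }
  }

  # Free ligand given free metals: L_T = L_f * (alpha_H + K_Ca Ca + K_Mg Mg)
  free_ligand <- function(ch, ca, mg) {
    ch$total_M / (ch$alpha_H + ch$K_Ca * ca + ch$K_Mg * mg)
  }
  bound_metal <- function(ca, mg, which) {
    s <- 0
    for (ch in chel) {
      lf <- free_ligand(ch, ca, mg)
      s <- s + if (which == "Ca") ch$K_Ca * ca * lf else ch$K_Mg * mg * lf
    }
    s
  }
  solve_mg <- function(ca) {
    if (mg_T == 0) return(0)
    f <- function(pmg) mg_T - 10^(-pmg) - bound_metal(ca, 10^(-pmg), "Mg")
    lo <- -log10(mg_T) - 1e-9
    if (f(lo) >= 0) return(mg_T) # nothing binds Mg
    10^(-stats::uniroot(f, c(lo, 30), tol = 1e-15)$root)
  }

  if (ca_T == 0) {
    ca <- 0
    mg <- solve_mg(0)
  } else {
    f_ca <- function(pca) {
      ca <- 10^(-pca)
      mg <- solve_mg(ca)
      ca_T - ca - bound_metal(ca, mg, "Ca")
    }
    lo <- -log10(ca_T) - 1e-9
    if (f_ca(lo) >= 0) {
      ca <- ca_T
    } else {
      pca <- stats::uniroot(f_ca, c(lo, 30), tol = 1e-15)$root
      # Newton polish on the log scale to push the residual to machine level
      for (i in 1:6) {
        r <- f_ca(pca)
        h <- 1e-7
        dr <- (f_ca(pca + h) - r) / h
        if (!is.finite(dr) || dr == 0) break
        step <- r / dr
        if (!is.finite(step) || abs(step) > 1) break
        pca <- pca - step
      }
      ca <- 10^(-pca)
    }
    mg <- solve_mg(ca)
  }

  species <- do.call(rbind, lapply(names(chel), function(nm) {
    ch <- chel[[nm]]
    lf <- if (ch$total_M > 0) free_ligand(ch, ca, mg) else 0
    data.frame(
      ligand = nm,
      total_mM = ch$total_M * 1e3,
      free_mM = lf * 1e3,
      protonated_mM = lf * (ch$alpha_H - 1) * 1e3,
      ca_bound_mM = ch$K_Ca * ca * lf * 1e3,
      mg_bound_mM = ch$K_Mg * mg * lf * 1e3,
      kd_app_uM = ch$alpha_H / ch$K_Ca * 1e6,
      stringsAsFactors = FALSE
    )
  }))

  ca_recovered <- ca + if (length(chel)) sum(species$ca_bound_mM) * 1e-3 else 0
  mg_recovered <- mg + if (length(chel)) sum(species$mg_bound_mM) * 1e-3 else 0
  rel_ca <- if (ca_T > 0) abs(ca_recovered - ca_T) / ca_T else 0
  rel_mg <- if (mg_T > 0) abs(mg_recovered - mg_T) / mg_T else 0
  if (max(rel_ca, rel_mg) > 1e-9) {
    stop(structure(class = c("cabuffer_numerical_error", "error", "condition"),
                   list(message = sprintf(
                     "speciation solve did not converge: relative mass-balance residual %.3g",
                     max(rel_ca, rel_mg)), call = sys.call(-1))))
  }

  structure(list(
    free_ca_uM = ca * 1e6,
    free_mg_mM = mg * 1e3,
    species = species,
    totals = c(Ca_mM = ca_T * 1e3, Mg_mM = mg_T * 1e3),
    residual_rel = max(rel_ca, rel_mg),
    ionic_strength = I,
    pH = solution$pH,
    temperature_C = tC,
    purity = purity
  ), class = "speciation_result")
}

#' @export
print.speciation_result <- function(x, ...) {
  cat("Calibration-solution speciation\n")
  cat(sprintf("  pH %.2f, %.0f C, ionic strength %.3f M\n",
              x$pH, x$temperature_C, x$ionic_strength))
  cat(sprintf("  free Ca2+: %.4g uM   free Mg2+: %.4g mM\n",
              x$free_ca_uM, x$free_mg_mM))
  if (!is.null(x$species) && nrow(x$species) > 0) {
    cat("  chelator species (mM):\n")
    print(x$species, row.names = FALSE, digits = 4)
  }
  invisible(x)
}
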