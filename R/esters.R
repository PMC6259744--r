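#' Describe one fluocinolone acetonide C-21 ester
#'
#' Bundles the identity and experiment-design constants of a single ester:
#' molar masses (used to convert the weighed mass to an initial molar
#' concentration), the weighed mass and mixture volume, the lipophilicity
#' and steric descriptors, and — for simulation only — the true
#' pseudo-first-order solvolytic rate constant.
#'
#' @param name short identifier, e.g. `"FA-21-Ac"`.
#' @param molar_mass molar mass of the ester (g/mol).
#' @param fa_molar_mass molar mass of the parent alcohol, fluocinolone
#'   acetonide (g/mol). Defaults to the monoisotopic FA mass.
#' @param initial_mass mass weighed into the solvolysis mixture (mg).
#' @param volume mixture volume (mL).
#' @param clogp calculated octanol–water logP (dimensionless).
#' @param steric_hindrance carbonyl-carbon steric hindrance descriptor
#'   (dimensionless, treated as opaque).
#' @param true_K pseudo-first-order rate constant (1/h) used only by the
#'   simulator; `NA` for esters whose kinetics are to be measured.
#'
#' @return An object of class `ester_record`.
#' @seealso [fa_esters()] for the six study esters,
#'   [initial_concentration()] for the mg-to-µmol/L conversion.
#' @export
#' @examples
#' ac <- ester_record("FA-21-Ac", molar_mass = 494.2116, initial_mass = 16,
#'                    volume = 100, true_K = 0.0615)
#' initial_concentration(ac)  # ~323.7 umol/L
ester_record <- function(name, molar_mass, fa_molar_mass = 452.20105,
                         initial_mass, volume, clogp = NA_real_,
                         steric_hindrance = NA_real_, true_K = NA_real_) {
  if (!is.character(name) || length(name) != 1L || !nzchar(name))
    ek_stop("'name' must be a non-empty string", "esterkin_validation_error")
  stopifnot_scalar_number(molar_mass, "molar_mass", positive = TRUE)
  stopifnot_scalar_number(fa_molar_mass, "fa_molar_mass", positive = TRUE)
  if (molar_mass <= fa_molar_mass)
    ek_stop("'molar_mass' must exceed 'fa_molar_mass' (an ester is heavier than its parent alcohol)",
            "esterkin_validation_error")
  stopifnot_scalar_number(initial_mass, "initial_mass", positive = TRUE)
  stopifnot_scalar_number(volume, "volume", positive = TRUE)
  if (!is.na(true_K)) stopifnot_scalar_number(true_K, "true_K", nonnegative = TRUE)
  structure(
    list(name = name, molar_mass = molar_mass, fa_molar_mass = fa_molar_mass,
         initial_mass = initial_mass, volume = volume, clogp = clogp,
         steric_hindrance = steric_hindrance, true_K = true_K),
    class = "ester_record"
  )
}

#' @export
print.ester_record <- function(x, ...) {
  cat(sprintf("<ester_record> %s\n", x$name))
  cat(sprintf("  molar mass %.4f g/mol (parent FA %.4f), %g mg / %g mL (c0 = %.2f umol/L)\n",
              x$molar_mass, x$fa_molar_mass, x$initial_mass, x$volume,
              initial_concentration(x)))
  cat(sprintf("  cLogP %s, steric hindrance %s, true K %s 1/h\n",
              format(x$clogp), format(x$steric_hindrance), format(x$true_K)))
  invisible(x)
}

#' Initial molar concentration of an ester mixture
#'
#' Converts the weighed mass to µmol/L: `initial_mass [mg] / molar_mass
#' [g/mol] / volume [mL] * 1e6`. All kinetics in the package are carried out
#' in molar units, so that the liberated-FA concentration equals the
#' concentration of solvolysed ester exactly.
#'
#' @param ester an [ester_record()].
#' @return Initial concentration c0 in µmol/L.
#' @export
initial_concentration <- function(ester) {
  if (!inherits(ester, "ester_record"))
    ek_stop("'ester' must be an ester_record", "esterkin_validation_error")
  ester$initial_mass / ester$molar_mass / ester$volume * 1e6
}

#' The six study esters
#'
#' Returns the fluocinolone acetonide C-21 esters of the study as a named
#' list of [ester_record()] objects. Molar masses are monoisotopic, derived
#' from the reported ESI-MS `[M+H]+` values (minus one proton mass); the FA
#' parent mass follows from FA-21-Ac stoichiometry. Weighed masses and the
#' 100 mL mixture volume are the published solvolysis design; cLogP, steric
#' hindrance and the measured rate constants come from the packaged
#' descriptor fixture. The measured K is stored as `true_K` so the records
#' can drive the simulator directly.
#'
#' @return Named list of six `ester_record` objects, in the fixture's
#'   column order.
#' @export
#' @examples
#' sapply(fa_esters(), initial_concentration)
fa_esters <- function() {
  tab <- utils::read.csv(table1_path("table1_esters.csv"))
  recs <- lapply(seq_len(nrow(tab)), function(i)
    ester_record(tab$ester[i], molar_mass = tab$molar_mass[i],
                 fa_molar_mass = tab$fa_molar_mass[i],
                 initial_mass = tab$initial_mass_mg[i],
                 volume = tab$volume_mL[i], clogp = tab$cLogP[i],
                 steric_hindrance = tab$steric_hindrance[i],
                 true_K = tab$K_per_h[i]))
  names(recs) <- tab$ester
  recs
}
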