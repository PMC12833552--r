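# Gas constant in kcal mol^-1 K^-1 (4 significant figures, the rounding
# conventional in binding free-energy work).
R_KCAL <- 1.987e-3

#' Labelled binding free energy record
#'
#' @param label description of the binding event (e.g. `"ternary"`,
#'   `"FKBP12-rapamycin"`).
#' @param dg mean binding free energy, kcal/mol.
#' @param sd standard deviation, kcal/mol (>= 0).
#' @param provenance `"printed"` (taken from a table) or
#'   `"computed-from-Kd"`.
#' @return An object of class `iw_energy_record`.
#' @export
energy_record <- function(label, dg, sd = 0,
                          provenance = c("printed", "computed-from-Kd")) {
  if (sd < 0) stop("SD must be >= 0")
  structure(list(label = label, dg = dg, sd = sd,
                 provenance = match.arg(provenance)),
            class = "iw_energy_record")
}

#' @export
print.iw_energy_record <- function(x, ...) {
  cat(sprintf("%s: dG = %.2f +/- %.2f kcal/mol (%s)\n",
              x$label, x$dg, x$sd, x$provenance))
  invisible(x)
}

#' Convert a dissociation constant to a binding free energy
#'
#' Standard-state conversion dG = R T ln(Kd / c0) with R = 1.987e-3
#' kcal/(mol K) and c0 = 1 mol/L. The uncertainty is propagated to first
#' order: sd(dG) = R T sd(Kd) / Kd. Values are kept at full precision;
#' rounding to two decimals happens only at presentation.
#'
#' @param kd dissociation constant, mol/L (> 0).
#' @param kd_sd standard deviation of Kd, mol/L.
#' @param temperature absolute temperature in K (default 298.15, i.e. 25 C).
#' @param label record label.
#' @return An [energy_record()] with provenance `"computed-from-Kd"`.
#' @export
kd_to_free_energy <- function(kd, kd_sd = 0, temperature = 298.15,
                              label = "binding") {
  if (!is.numeric(kd) || kd <= 0) stop("Kd must be positive")
  if (temperature <= 0) stop("temperature must be positive")
  dg <- R_KCAL * temperature * log(kd)     # c0 = 1 M
  sd <- R_KCAL * temperature * kd_sd / kd
  rec <- energy_record(label, dg, sd, provenance = "computed-from-Kd")
  rec
}

#' Cooperative free energy of a ternary complex
#'
#' The cooperative free energy is the binding free energy of the ternary
#' complex (target protein binding to the preformed effector-glue binary
#' complex) minus the binding free energy of the target-protein/molecular-glue
#' binary complex. Negative values indicate positive cooperativity: the glue
#' makes the protein-protein association more favourable. Standard
#' deviations combine in quadrature (independent errors).
#'
#' @param ternary [energy_record()] for the ternary complex.
#' @param binary_target_glue [energy_record()] for the target-glue binary
#'   complex.
#' @return An object of class `iw_coop_result` with fields `dg`, `sd` and
#'   the two component records.
#' @export
cooperativity <- function(ternary, binary_target_glue) {
  dg <- ternary$dg - binary_target_glue$dg
  sd <- sqrt(ternary$sd^2 + binary_target_glue$sd^2)
  structure(list(dg = dg, sd = sd, ternary = ternary,
                 binary_target_glue = binary_target_glue),
            class = "iw_coop_result")
}

#' @export
print.iw_coop_result <- function(x, ...) {
  cat(sprintf("cooperative free energy: %.2f +/- %.2f kcal/mol\n",
              x$dg, x$sd))
  invisible(x)
}

#' Free-energy bookkeeping table
#'
#' Builds the binding/cooperativity table for a set of labelled inputs.
#' Each entry is either a printed dG (mean, sd) or a Kd measurement
#' (converted via [kd_to_free_energy()]). Rows flagged as ternary are paired
#' with the named target-glue binary row to compute cooperative free
#' energies.
#'
#' @param entries data.frame with columns `label`, `kind` (`"dg"` or
#'   `"kd"`), `value`, `sd`, optional `temperature` (K, for `kd` rows),
#'   optional `ternary_of` naming the binary-complex label a ternary row is
#'   compared against.
#' @return data.frame with columns `label`, `dg`, `sd`, `provenance`,
#'   `coop_dg`, `coop_sd` (coop columns NA for non-ternary rows), numeric at
#'   full precision.
#' @export
thermo_table <- function(entries) {
  need <- c("label", "kind", "value", "sd")
  if (!all(need %in% names(entries)))
    stop("entries needs columns: ", paste(need, collapse = ", "))
  recs <- list()
  for (i in seq_len(nrow(entries))) {
    e <- entries[i, ]
    recs[[e$label]] <- if (e$kind == "kd") {
      temp <- if ("temperature" %in% names(entries) && !is.na(e$temperature))
        e$temperature else 298.15
      kd_to_free_energy(e$value, e$sd, temperature = temp, label = e$label)
    } else {
      energy_record(e$label, e$value, e$sd, provenance = "printed")
    }
  }
  out <- data.frame(
    label = names(recs),
    dg = vapply(recs, function(r) r$dg, numeric(1)),
    sd = vapply(recs, function(r) r$sd, numeric(1)),
    provenance = vapply(recs, function(r) r$provenance, character(1)),
    coop_dg = NA_real_, coop_sd = NA_real_,
    stringsAsFactors = FALSE)
  if ("ternary_of" %in% names(entries)) {
    for (i in seq_len(nrow(entries))) {
      ref <- entries$ternary_of[i]
      if (!is.na(ref) && nzchar(ref)) {
        if (!ref %in% names(recs))
          stop("ternary_of refers to unknown label: ", ref)
        cc <- cooperativity(recs[[entries$label[i]]], recs[[ref]])
        out$coop_dg[out$label == entries$label[i]] <- cc$dg
        out$coop_sd[out$label == entries$label[i]] <- cc$sd
      }
    }
  }
  rownames(out) <- NULL
  out
}

#' Read a plain-text thermodynamics input table
#'
#' TSV with the columns described in [thermo_table()].
#'
#' @param path input path.
#' @return data.frame of entries.
#' @export
read_thermo_entries <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                    stringsAsFactors = FALSE)
}
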