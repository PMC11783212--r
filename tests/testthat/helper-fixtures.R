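# Shared fixtures, built once per test run (memoized in the helper env).

.fix <- new.env(parent = emptyenv())

fixture <- function(name, expr) {
  if (is.null(.fix[[name]])) .fix[[name]] <- force(expr)
  .fix[[name]]
}

fix_monomer <- function(preset = "rad52-long", seed = 7L, ...) {
  fixture(paste0("mono_", preset, "_", seed),
          make_ssap_monomer(preset_family_params(preset, seed = seed, ...)))
}

fix_family <- function(preset = "rad52-long", n = 10L, seed = 42L, sigma = 0.5) {
  fixture(sprintf("fam_%s_%d_%d_%g", preset, n, seed, sigma),
          make_family(n, preset_family_params(preset, seed = seed),
                      divergence_sigma = sigma, family = preset))
}

# Minimal hand-written PDB text: 3 residues with B-factors 80, 90, 70.
pdb3_text <- function() {
  paste(c(
    "ATOM      1  N   ALA A   1       0.000   0.000   0.000  1.00 80.00           N",
    "ATOM      2  CA  ALA A   1       1.458   0.000   0.000  1.00 80.00           C",
    "ATOM      3  C   ALA A   1       2.009   1.420   0.000  1.00 80.00           C",
    "ATOM      4  N   GLY A   2       3.332   1.536   0.000  1.00 90.00           N",
    "ATOM      5  CA  GLY A   2       3.988   2.839   0.000  1.00 90.00           C",
    "ATOM      6  C   GLY A   2       5.504   2.693   0.000  1.00 90.00           C",
    "ATOM      7  N   TRP A   3       6.139   3.857   0.000  1.00 70.00           N",
    "ATOM      8  CA  TRP A   3       7.592   3.905   0.000  1.00 70.00           C",
    "END"), collapse = "\n")
}

# StructureModel with a constant confidence, trivial geometry.
const_conf_model <- function(id, conf, n = 10L) {
  structure_model(id = id, resname = rep("ALA", n), ca = make_strand(n),
                  conf = rep(conf, n))
}

fake_comp <- function(sh, ss, hh, hs) {
  structure(list(sheet_h = sh, sheet_s = ss, hairpin_h = hh, hairpin_s = hs,
                 empty_transfer = FALSE), class = "MotifComposition")
}

# A ScreenResult-like object without running alignments.
fake_screen_result <- function(id, tms) {
  best <- max(tms)
  structure(list(id = id, tm_per_rep = tms, best_tm = best,
                 tier = if (best < 0.5) "below" else if (best > 0.7) "high"
                        else "moderate"),
            class = "ScreenResult")
}
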