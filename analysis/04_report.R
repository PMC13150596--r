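#!/usr/bin/env Rscript
# Render the two run directories as markdown reports: explained variance,
# HCA purity, selected wavelengths/wavenumbers with Fisher-weight class
# attribution and nearest literature band assignment, and figures of merit
# (LOO-CV and test, both class orientations).

library(chemodisc)

for (modality in c("uv", "ftir")) {
  run_dir <- sprintf("results/run_%s", modality)
  path <- sprintf("results/report_%s.md", modality)
  render_report(run_dir, path)
  message("wrote ", path)
}
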