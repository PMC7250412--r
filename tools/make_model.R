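#!/usr/bin/env Rscript
# Regenerates the packaged model files under inst/extdata/ from the code
# constructors.  Run from the package root after changing any default
# parameter.
library(txasim)
write_network(coagulation_cascade_network(), "inst/extdata/coagulation_cascade.json")
write_network(build_full_network(), "inst/extdata/txa_fibrinolysis_model.json")
cat("wrote", file.size(list.files("inst/extdata", full.names = TRUE)), "bytes\n")
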