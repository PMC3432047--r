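#!/usr/bin/env Rscript
# Growth on the 35-source catalogue, each normalized to 1 mmol carbon
# atoms/gDW/h, NGAM 0.67; biomass relative to glucose = 100.
suppressPackageStartupMessages(library(sulfoflux))
dir.create("results", showWarnings = FALSE)

model <- build_ccm_model()
scan <- run_carbon_source_scan(model, read_carbon_source_catalogue(),
                               ngam = 0.67)
scan <- scan[order(-scan$relative_to_glucose, scan$source), ]
utils::write.table(scan, "results/carbon_scan.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
ok <- scan[scan$status == "ok", ]
message("best source per carbon: ", ok$source[1], " (",
        round(ok$relative_to_glucose[1]), "% of glucose)")
message("disaccharides/oligosaccharides above glucose: ",
        paste(ok$source[ok$carbons >= 12 & ok$relative_to_glucose > 100],
              collapse = ", "))
message(sum(scan$status == "unsupported"), " catalogue sources lack curated ",
        "routes and are reported as unsupported")
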