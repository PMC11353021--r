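#!/usr/bin/env Rscript
# Registry-level arithmetic: rebuild the one-year exam mix deterministically
# from its printed per-protocol counts, then recompute study totals,
# protocol shares and the per-study recurrent-CT rate.

library(cedlar)
dir.create("results", showWarnings = FALSE)

mix <- load_exam_mix_fixture()
reg <- registry_from_exam_mix(mix)
tab <- build_exam_mix_table(reg$records, reg$patients,
                            "2021-01-01", "2021-12-31")
write.csv(tab, "results/exam_mix.csv", row.names = FALSE)

rate <- recurrent_ct_rate(reg$records, "2021-01-01", "2021-12-31")
cat(sprintf("%d CT studies over the year; largest protocol %s at %.1f%%.\n",
            attr(tab, "total_ct"), tab$protocol[1], tab$pct[1]))
cat(sprintf("Recurrent CT studies: %d of %d (%.1f%%).\n",
            rate$recurrent_count, rate$total_ct_count, 100 * rate$rate))
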