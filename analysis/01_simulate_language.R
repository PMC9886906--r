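#!/usr/bin/env Rscript
# Step 1: generate the artificial language and inspect its psycholinguistic
# structure (frequency, rime consistency, neighbourhood, imageability proxy,
# homophony), then write it out as TSV for the later steps.

suppressPackageStartupMessages(library(triread))
dir.create("results", showWarnings = FALSE)

spec <- language_spec()          # 300 words, 20% rime exceptions, 2 homophone pairs
lex <- build_language(spec)
print(lex)

it <- lex$items
cat(sprintf("exception fraction: %.3f (target %.2f)\n",
            mean(it$is_exception), spec$exception_fraction))
cat(sprintf("rime consistency: %.2f-%.2f (mean %.2f)\n",
            min(it$rc), max(it$rc), mean(it$rc)))
cat(sprintf("neighbourhood size: 0-%d (mean %.1f)\n", max(it$ons), mean(it$ons)))
cat(sprintf("imageability proxy (active features): %d-%d\n",
            min(it$img), max(it$img)))
cat(sprintf("top-10 words carry %.1f%% of token frequency\n",
            100 * sum(sort(it$wf, decreasing = TRUE)[1:10])))

write_lexicon(lex, "results/language")
nw <- rbind(generate_nonwords(lex, 80, "consistent", seed = 1001),
            generate_nonwords(lex, 80, "inconsistent", seed = 1002))
nw_flat <- data.frame(letters = nw$letters, condition = nw$condition,
                      acceptable = vapply(nw$acceptable, function(a)
                        paste(vapply(a, paste, character(1), collapse = " "),
                              collapse = " | "), character(1)))
write.table(nw_flat, "results/nonwords.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)
cat("wrote results/language_items.tsv, results/language_inventory.tsv,",
    "results/nonwords.tsv\n")
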