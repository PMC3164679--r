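#!/usr/bin/env Rscript
# Step 1 — simulate the study corpus.
#
# Six synthetic speakers utter every consonant {b, p, d, t} before every
# coarticulating phone {a, e, i, o, u, r, s} in word-initial and word-medial
# position: 336 synchronized audio + articulograph-trajectory records with
# ground-truth plosion landmarks. Output: WAV + TSV per utterance and a
# manifest under scratch/corpus/, plus a design summary under results/.

source("analysis/_common.R")

corpus <- make_corpus(6, 1, seed = SEED, CFG)
write_corpus(corpus, CORPUS_DIR)

design <- as.data.frame(table(speaker = corpus$manifest$speaker,
                              class = corpus$manifest$class))
write_result_csv(design, file.path(RESULTS_DIR, "corpus_design.csv"), CFG, SEED)

cat("wrote", nrow(corpus$manifest), "utterances to", CORPUS_DIR, "\n")
cat("class balance:",
    sum(corpus$manifest$class == "bilabial"), "bilabial /",
    sum(corpus$manifest$class == "dental"), "dental\n")
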