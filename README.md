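# biotriage

Evidence-centric text classification for biocuration workflows.

Curation teams that maintain molecular-interaction databases must decide
which papers contain curatable experimental evidence (document **triage**)
and which experimental **method** a given piece of evidence reports. Both
decisions hinge on evidence-bearing text — figure captions and the
"evidence fragments" of narrative that describe each figure — rather than
on the paper as a whole. `biotriage` implements that pipeline end to end
for R users:

* a JATS-subset article model (title, abstract, MeSH terms, body
  paragraphs, figure captions) with readers/writers, a biomedical-aware
  tokenizer and a sentence splitter;
* figure/panel reference detection (`Fig. 2B`, `(Figures 1A and 1C-E)`)
  and deterministic per-subfigure evidence-fragment extraction;
* word-embedding tables in the standard word-vector text format, with
  explicit padding and out-of-vocabulary contracts;
* passage-level method classifiers (CNN and LSTM heads over frozen
  embeddings) for grouped PSI-MI-style detection-method codes;
* a document triage classifier: each selected passage is encoded by a
  CNN–bidirectional-LSTM, passage vectors are aggregated with additive
  attention, and a fully connected sigmoid layer makes the decision —
  attention weights are returned so you can see *which* passages drove it;
* a synthetic-corpus generator with plantable, localized class signal, so
  the whole pipeline is testable without any external data;
* a seeded experiment runner with tidy, reproducible reports, plus a thin
  CLI (`exec/biotriage`).

The attention aggregation computes, for passage vectors `h_i`,

```
score_i = v' tanh(W h_i + b)      w = softmax(score)      d = Σ_i w_i h_i
```

and the triage probability is `sigmoid(u'd + c)`. The networks are small
and implemented directly in R matrix code with exact backpropagation
(verified against finite differences in the test suite); no deep-learning
framework is required.

## Worked example

Generate a synthetic triage corpus whose positive documents carry signal
tokens only in figure captions, then train the captions-source classifier
with two random restarts:

```r
library(biotriage)

find_figure_references("(Figures 1A and 1C-E)")
#> # A tibble: 2 × 5
#>   figure panels    start   end match
#>    <int> <list>    <int> <int> <chr>
#> 1      1 <chr [1]>     1    11 Figures 1A
#> 2      1 <chr [3]>    16    20 1C-E

corpus <- generate_triage_corpus(
  synth_config(n_docs = 600, signal_location = "captions",
               signal_p = 0.8, seed = 1))
emb <- attr(generate_toy_embeddings(corpus_vocab(corpus$docs),
                                    dim = 50, seed = 1), "table")
cfg <- triage_config("captions", max_len = 64, n_filters = 32,
                     lstm_units = 32, attention_width = 32,
                     dropout = 0.25, lr = 2e-3, epochs = 8, seed = 1)
ev <- triage_multirestart(corpus$docs, corpus$labels$label, cfg, emb,
                          n_restarts = 2)
ev
#> <bt_eval> triage/captions: accuracy 0.958 ± 0.012 over 2 restart(s)
```

The held-out accuracy (mean ± sd over restarts) is far above the ~0.54
majority baseline because the classifier finds the caption-localized
signal; retraining with `text_source = "abstract"` on the same corpus stays
at the baseline, since abstracts carry no signal. `tidy(ev)` returns the
per-restart accuracies, `glance(ev)` a one-row summary, and
`classify_document(model, doc)` returns the relevance probability together
with per-passage attention weights (`plot_attention()` displays them).

Evidence extraction works on real JATS XML as well:

```r
doc    <- read_document("paper.nxml", dialect = "jats")
frags  <- extract_evidence_fragments(doc)    # tibble: figure, panels, text
caps   <- caption_for(doc, figure = 1, panels = "A")
```

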