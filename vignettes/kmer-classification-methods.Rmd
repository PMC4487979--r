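---
title: "K-mer based genus classification: models, parameters and design"
author: "kmerTax"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{K-mer based genus classification: models, parameters and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kmerTax)
```

## The problem

Assigning a 16S rRNA gene sequence to a genus is a pattern-recognition
task: given a reference set of labelled sequences, decide which genus a new
sequence most resembles.  Word-count (K-mer) methods sidestep alignment
entirely: a sequence of length $L$ is represented by the counts of its
$L - K + 1$ overlapping words of length $K$, a vector in a
$D = 4^K$-dimensional space.  All classifiers in this package share that
feature space — the $4^K$ words in alphabetical order over A < C < G < T,
in which the last letter varies fastest, so each run of four consecutive
words shares one $K-1$-base *pretext* — and differ only in how the counts
are modelled.

Three representations of a count vector are used (`countKmers()`,
`asPresence()`, `asProfile()`):

* **presence**: 0/1 indicators of word occurrence,
* **frequency**: raw overlapping counts,
* **profile**: counts divided by their sum (multinomial probabilities).

Counting is case-insensitive, maps U to T (so rRNA and rDNA input behave
identically), and *skips* any window containing a symbol outside
A, C, G, T rather than imputing it.  A query in which no window is
countable carries no evidence and is always reported `"unclassified"`.

## The five classifiers

**RDP-style naive Bayes** (`trainRdp()`) uses presence/absence.  With
$n_j$ the number of training sequences containing word $w_j$ and $N$ the
total, the background probability is

$$\Pr(w_j) = \frac{n_j + 0.5}{N + 1},$$

and for genus $g$ with $M_g$ sequences, $m_{g,j}$ of which contain $w_j$,

$$q_{g,j} = \frac{m_{g,j} + \Pr(w_j)}{M_g + 1}.$$

The pseudo-terms keep every probability strictly inside $(0, 1)$.
Classification computes the score vector
$z = p + L\,a'$, where $L = \log_2 Q$, $a$ is the query's presence vector
and $p$ the vector of log2 priors; the query is assigned to the genus with
the unique maximum of $z$.  With flat priors $p$ is a shared constant and
is represented as the zero vector — it cannot change the argmax.
Abundance priors ($p_g = \log_2 M_g/N$) are also available.

**Multinomial naive Bayes** (`trainMultinomial()`) uses frequencies.  Per
genus the pooled, size-scaled frequencies are pseudo-counted,
$F(w_j\mid g) = m_{g,j}/M_g + 1/D$ (here $m_{g,j}$ is the *summed
frequency*, not a sequence count), and row-normalized into multinomial
probabilities $q_{g,j} = F(w_j\mid g)/\sum_k F(w_k\mid g)$.  Scoring is
again $z = p + L\,a'$ with the query's frequency vector.  The multinomial
coefficient is constant per query, so ranking these scores ranks the exact
multinomial likelihoods — a property the test suite verifies against a
`lgamma`-based oracle.

**Markov** (`trainMarkov()`) estimates transition probabilities of the
last letter of a word given its pretext.  From the same pseudo-counted
$F$, each pretext's four extensions are normalized to sum to one:
$q_{g,j} = F(w_j\mid g) / \sum_{k \in \text{block}(j)} F(w_k\mid g)$,
where block($j$) is the run of four consecutive dictionary words sharing
$w_j$'s pretext.  Pretexts never observed in a genus fall back to uniform
(1/4) transitions through the pseudo-counts.  Scoring is $z = L\,a'$ with
no prior term.  Requires $K \ge 2$.

**Nearest neighbour** (`trainNn()`) stores one multinomial profile per
training sequence and assigns a query the genus of its Euclidean-nearest
reference row.  If rows of two or more distinct genera tie for the
minimum distance, the query is `"unclassified"`.

**PLS-preprocessed nearest neighbour** (`trainPlsnn()`) first maps the
$D$-dimensional profile space into a $C$-dimensional subspace with
supervised partial least squares (PLS2), using the genus indicator matrix
$Y$ ($N \times G$, one 1 per row) as the response, then runs the same
nearest-neighbour rule on the training scores.  The subspace is chosen to
maximize covariance with genus membership, damping within-genus variation
relative to between-genus variation before distances are measured.

### The shared tie rule

All methods assign by argmax over genera.  Exact floating-point equality
is a fragile tie criterion, so ties are declared whenever
$|z_{\max} - z_g| \le 10^{-12}\max(1, |z_{\max}|)$; a tie between two or
more genera yields `"unclassified"`.  Abstention is deliberately counted
as an error by the evaluation layer: a benchmark that rewarded silence
would understate the practical error rate.

## The PLS fit in detail

`fitPls()` extracts components sequentially from the column-centered
blocks $X_c$, $Y_c$ with classical NIPALS deflation.  Rather than running
the NIPALS inner power iteration, each weight vector is computed directly
at its fixed point: $w \propto X_c'Y_c v$, where $v$ is the dominant
eigenvector of the small $G \times G$ matrix $(Y_c'X_c)(X_c'Y_c)$.  This
is algebraically the converged NIPALS solution, exact and fast when
$G \ll D$; agreement with an independent PLS2 implementation
(`mixOmics::pls`) is part of the test suite (scores equal up to column
sign at $10^{-5}$).

Choices that were genuinely open, and how they were fixed:

* **Centering, no scaling.** $X$ and $Y$ columns are mean-centered
  (queries are centered with the *training* means); profiles already live
  on one scale, so unit-variance scaling would only amplify rare-word
  noise.
* **Projection matrix.** The orthonormal weight matrix $W$ serves as the
  projection $R$, so a query maps as $s = (a - \bar x)R$ and the mapping
  is non-expansive (subspace distances never exceed centered profile
  distances).  The stored reference rows are the NIPALS scores $S$.  For
  $C > 1$, $X_c R$ and $S$ differ slightly (the familiar NIPALS deflation
  discrepancy); the identity $S R' = X_c R R'$ is exact at $C = 1$ and
  the decomposition $X_c = S P'$ becomes exact at full rank, and both are
  asserted in the tests at those settings.
* **Degenerate input.** Component extraction stops early, with a warning
  and a truncated fit, once the residual $X$ variance falls below
  $10^{-12}$ of its initial value, so rank-deficient training sets cannot
  produce numerical junk components.
* **Subspace dimension.** `dimensionGrid(N, K)` produces the candidate
  grid: $C_{\max} = \min(N - 1,\ 4^K - 1,\ 2000)$ and
  $C = \mathrm{round}(i\,C_{\max}/8)$, $i = 1,\dots,8$.  Model selection
  over this grid is a benchmarking loop the user runs explicitly (e.g.
  with `runCrossValidation()` per $C$); `trainPlsnn()` defaults to the
  middle grid value but never selects $C$ silently.

## The benchmarking protocol

`makeCvFolds()` orders records alphabetically by genus (ties broken by
sequence id, for run-to-run determinism) and deals them round-robin into
10 folds, so every genus is spread as evenly as possible: a genus of size
$s \le 10$ occupies $s$ distinct folds.  `runCrossValidation()` holds each
fold out once, trains on the rest, and classifies the held-out sequences
either full-length or as fragments.

**Fragments.** `fragmentSequence()` cuts a sequence of length $L$ into
$n = 10$ pieces of 200 bases whose 0-based starts are
$\mathrm{round}((i-1)(L - 200)/(n-1))$: the first fragment starts at the
first base, the last ends at the last base, and adjacent fragments overlap
whenever $L < 2000$.  Evenly spaced starts with pinned endpoints is the
minimal scheme that covers the gene end to end with partial overlap; both
$n$ and the fragment length are configurable.  Only *test* sequences are
fragmented — training always sees full-length sequences — and all
fragments are pooled as independent queries in the error computation.

**Singletons.** A genus with exactly one sequence can never be recovered
under cross-validation: when its sequence is tested, the genus is absent
from training.  Such sequences stay in the corpus (they still shape the
trained models) but are excluded from every reported error denominator
(`singletonGenera()`, `classificationError()`).

**Breakdowns.** `errorByGenusSize()` averages per-genus error rates within
each full-data genus size (mean of genus means, so one large genus cannot
swamp the size class); `positionalError()` splits the fragment error by
fragment index; `errorSetOverlap()` partitions the union of the methods'
error sets into Venn sectors and counts how many all-method errors
received the identical wrong genus everywhere.

## The synthetic community generator

`simulateCommunity()` emulates the statistical structure that makes this
classification problem what it is, without requiring any external corpus:
a uniform-random root sequence; per genus an ancestor mutated from the
root at per-site rate `dBetween` (default 0.25); per sequence a leaf
mutated from its ancestor at rate `dWithin` (default 0.01); substitutions
i.i.d. per site, uniform over the three alternative bases, no indels.
Defaults follow the target application: ~1500-base sequences (full-length
16S), many genera, and — via `sampleGenusSizes()`, a truncated discrete
power law with exponent 2.5 — strongly right-skewed genus sizes in which
singletons are the most common class.  Given a seed the corpus is
byte-identical across runs.

What this generator deliberately does *not* reproduce: the
conserved/hypervariable region architecture of real 16S genes (so
per-fragment-position error profiles are flat here, unlike real data where
some regions are far more informative), insertions/deletions, sequencing
error, chimeras, and non-star phylogenetic structure within genera.
Passing the recovery benchmarks therefore demonstrates that the
implementations are correct and the pipeline is sound — not that any
particular error level will be achieved on curated reference sets, whose
label noise and uneven divergence dominate real-world error rates.

## Problem sizes used in the checks

The end-to-end recovery benchmark uses a community of 30 genera — 26 with
sizes drawn uniformly from 5–20 plus 4 singleton genera (so the singleton
bookkeeping is exercised, not just assumed) — with 1500-base sequences at
divergences 0.25/0.01 and word length $K = 6$ ($D = 4096$).  At these
settings all five classifiers reach 0 % cross-validated error on
non-singleton sequences, every singleton test sequence is wrong or
unclassified, the presence/absence classifier collapses at $K = 2$ (word
saturation: nearly every dinucleotide occurs in every sequence), and
fragment-mode error never falls below full-length error.  Oracle and
invariant suites run on deliberately small instances ($D = 16$ or $64$,
corpora of a few dozen sequences, 100 replicate corpora for the
normalization properties) where brute-force enumeration is exact and fast.

## Known limitations

* Genus is the only rank modelled; lineage strings are parsed but ranks
  above genus are discarded.
* No bootstrap confidence estimates accompany assignments; the score
  margin reported by `classifySequences()` is a raw gap, not a calibrated
  confidence.
* Words are counted on the given strand only (no reverse-complement
  canonicalization), matching the convention of the classifiers modelled.
* The Markov classifier is included for completeness of the comparison;
  on both full-length sequences and fragments it is the weakest and least
  stable of the five methods.
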