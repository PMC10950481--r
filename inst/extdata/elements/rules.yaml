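elements:
  TATA:
    category: upstream
    window:
    - -36
    - -24
    citation: TATA box consensus
  Inr:
    category: initiator
    window:
    - -4
    - 4
    citation: human initiator consensus; A+1 at motif offset 2
  dInr:
    category: initiator
    window:
    - -4
    - 4
    citation: Drosophila initiator consensus; A+1 at motif offset 2
  BBCA+1BW:
    category: initiator
    window:
    - -5
    - 4
    citation: BBCA+1BW initiator consensus; A+1 at motif offset 3
  DPE:
    category: downstream
    window:
    - 24
    - 35
    citation: downstream promoter element consensus; functional at +28..+33 from initiator
      A+1
  MTE:
    category: downstream
    window:
    - 15
    - 28
    citation: motif ten element consensus
  BREu:
    category: upstream
    window:
    - -40
    - -30
    citation: TFIIB recognition element, upstream of the TATA box
  BREd:
    category: upstream
    window:
    - -26
    - -17
    citation: TFIIB recognition element, downstream of the TATA box
  TCT:
    category: initiator
    window:
    - -4
    - 4
    citation: human polypyrimidine (TCT) initiator; C+1 at motif offset 2
  dTCT:
    category: initiator
    window:
    - -4
    - 4
    citation: Drosophila polypyrimidine (TCT) initiator; C+1 at motif offset 2
  Bridge:
    category: downstream
    window:
    - 15
    - 35
    citation: bipartite bridge element, coarse single-matrix form (uninformative spacer
      columns)
  PB:
    category: pausing
    window:
    - 20
    - 32
    citation: pause button, Pol II pausing-associated downstream motif
  Motif1:
    category: pausing
    window:
    - -10
    - 1
    citation: Ohler motif 1, promoter-proximal pausing-associated motif
  GAGA:
    category: pausing
    citation: GAGA factor binding site (GAGAG repeat, CIS-BP M5247-style)
rules:
- dependent: DPE
  anchor: dInr
  min_spacing: 28
  max_spacing: 33
- dependent: DPE
  anchor: Inr
  min_spacing: 28
  max_spacing: 33
- dependent: MTE
  anchor: dInr
  min_spacing: 18
  max_spacing: 22
- dependent: MTE
  anchor: Inr
  min_spacing: 18
  max_spacing: 22
- dependent: Bridge
  anchor: dInr
  min_spacing: 18
  max_spacing: 33
- dependent: Bridge
  anchor: Inr
  min_spacing: 18
  max_spacing: 33
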