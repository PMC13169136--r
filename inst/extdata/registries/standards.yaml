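# Compounds for which an authentic standard was co-analysed. Lookup is exact
# on the canonical name or any synonym. stereo: true marks standards whose
# comparison also confirms stereochemistry (grade A2); others grade B or C
# per the configured policy.
standards:
  - name: neochlorogenic acid
    synonyms: ["3-caffeoylquinic acid"]
    stereo: true
  - name: chlorogenic acid
    synonyms: ["5-caffeoylquinic acid"]
    stereo: true
  - name: 3,4-dicaffeoylquinic acid
    stereo: true
  - name: 1,5-dicaffeoylquinic acid
    stereo: true
  - name: 3,5-dicaffeoylquinic acid
    stereo: false
  - name: 4,5-dicaffeoylquinic acid
    stereo: false
  - name: leontopodic acid A
    synonyms: ["hydroxybutanyl-tricaffeoylhexaric acid"]
    stereo: false
  - name: leontopodic acid B
    synonyms: ["tricaffeoylhexaric acid"]
    stereo: false
  - name: rutin
    synonyms: ["quercetin rutinoside"]
    stereo: false
  - name: luteolin 7-O-glucoside
    synonyms: ["luteolin hexoside", "luteolin/kaempferol hexoside"]
    stereo: false
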