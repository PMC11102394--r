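# The 22 functional topics retained from the NeuroSynth v5-topics-50 release
# (July 2018 snapshot), with their selected key terms in decreasing order of
# centrality. Topic ids are the original topic numbers in that release.
topics:
  - id: 1
    name: trait
    terms: [trait, traits, personality]
  - id: 7
    name: reward
    terms: [reward, rewards, feedback, anticipation]
  - id: 8
    name: mind
    terms: [mind, tom]
  - id: 9
    name: working
    terms: [working, wm, load]
  - id: 11
    name: training
    terms: [training, trained, practice, sequence]
  - id: 13
    name: fear
    terms: [fear, threat]
  - id: 16
    name: inhibition
    terms: [inhibition, inhibitory, stop]
  - id: 17
    name: sensorimotor
    terms: [sensorimotor, finger]
  - id: 18
    name: number
    terms: [number, numerical, arithmetic, magnitude]
  - id: 19
    name: action
    terms: [action, actions, observation, mirror]
  - id: 20
    name: conflict
    terms: [conflict, interference, incongruent]
  - id: 25
    name: location
    terms: [location, space]
  - id: 26
    name: emotion
    terms: [emotion, affective, valence]
  - id: 28
    name: empathy
    terms: [empathy, empathic, moral]
  - id: 30
    name: decision
    terms: [decision, decisions, choice, choices, risky]
  - id: 31
    name: prediction
    terms: [prediction, predictive, predictions, classification]
  - id: 33
    name: encoding
    terms: [encoding, episodic, retrieval]
  - id: 37
    name: word
    terms: [word, sentences, sentence, reading]
  - id: 38
    name: objects
    terms: [objects, category]
  - id: 40
    name: face
    terms: [face, faces, facial, expressions]
  - id: 41
    name: events
    terms: [events, scenes, scene]
  - id: 47
    name: attention
    terms: [attention, attentional]
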