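# Example eegbench configuration: a reduced design with the planted
# discriminative channel on FP2-F4.
nSubjects = 4
videosPerEmotion = 3
segmentsPerVideo = 10
channels = FP2-F4, FP2-F8, FP1-F3, FP1-F7
samplingRate = 256
segmentSeconds = 10
separation = 1
signatureChannel = FP2-F4
noiseLevel = 1
subjectSd = 0.05
k = 200
seed = 7
trainFraction = 0.7
scalingMode = train-only
standardizeMode = segment
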