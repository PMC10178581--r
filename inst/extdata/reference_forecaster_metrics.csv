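model,MAE,MSE,RMSE,MAPE,SMAPE
RNN,0.28169,0.04516,0.88492,0.55132,7.32437
LSTM,0.24352,0.04324,0.83203,0.43147,6.43174
Transformer,0.16428,0.03986,0.28255,0.19966,2.43713
Autoformer,0.11017,0.01358,0.04681,0.11654,0.13005
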