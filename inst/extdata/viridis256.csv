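r,g,b
0.266667,0.00392157,0.3294118
0.266667,0.00784314,0.3372549
0.270588,0.01568627,0.3411765
0.270588,0.01960784,0.3490196
0.274510,0.02745098,0.3529412
0.274510,0.03137255,0.3607843
0.274510,0.03921569,0.3647059
0.274510,0.04313725,0.3686275
0.278431,0.05098039,0.3764706
0.278431,0.05490196,0.3803922
0.278431,0.06274510,0.3882353
0.278431,0.06666667,0.3921569
0.278431,0.07450980,0.3960784
0.282353,0.07843137,0.4039216
0.282353,0.08627451,0.4078431
0.282353,0.09019608,0.4117647
0.282353,0.09411765,0.4156863
0.282353,0.10196078,0.4235294
0.282353,0.10588235,0.4274510
0.282353,0.10980392,0.4313725
0.282353,0.11372549,0.4352941
0.282353,0.12156863,0.4392157
0.282353,0.12549020,0.4431373
0.282353,0.12941176,0.4509804
0.282353,0.13725490,0.4549020
0.282353,0.14117647,0.4588235
0.282353,0.14509804,0.4627451
0.282353,0.14901961,0.4666667
0.282353,0.15686275,0.4705882
0.282353,0.16078431,0.4745098
0.278431,0.16470588,0.4784314
0.278431,0.17254902,0.4784314
0.278431,0.17647059,0.4823529
0.278431,0.18039216,0.4862745
0.278431,0.18431373,0.4901961
0.274510,0.18823529,0.4941176
0.274510,0.19607843,0.4941176
0.274510,0.20000000,0.4980392
0.274510,0.20392157,0.5019608
0.270588,0.20784314,0.5058824
0.270588,0.21568627,0.5058824
0.270588,0.21960784,0.5098039
0.266667,0.22352941,0.5137255
0.266667,0.22745098,0.5137255
0.266667,0.23137255,0.5176471
0.262745,0.23921569,0.5176471
0.262745,0.24313725,0.5215686
0.258824,0.24705882,0.5215686
0.258824,0.25098039,0.5254902
0.258824,0.25490196,0.5254902
0.254902,0.25882353,0.5294118
0.254902,0.26666667,0.5294118
0.250980,0.27058824,0.5333333
0.250980,0.27450980,0.5333333
0.247059,0.27843137,0.5333333
0.247059,0.28235294,0.5372549
0.243137,0.28627451,0.5372549
0.243137,0.29019608,0.5372549
0.243137,0.29803922,0.5411765
0.239216,0.30196078,0.5411765
0.239216,0.30588235,0.5411765
0.235294,0.30980392,0.5411765
0.235294,0.31372549,0.5450980
0.231373,0.31764706,0.5450980
0.231373,0.32156863,0.5450980
0.227451,0.32549020,0.5450980
0.227451,0.32941176,0.5490196
0.223529,0.33333333,0.5490196
0.223529,0.33725490,0.5490196
0.219608,0.34509804,0.5490196
0.219608,0.34901961,0.5490196
0.215686,0.35294118,0.5490196
0.215686,0.35686275,0.5529412
0.211765,0.36078431,0.5529412
0.211765,0.36470588,0.5529412
0.207843,0.36862745,0.5529412
0.207843,0.37254902,0.5529412
0.203922,0.37647059,0.5529412
0.203922,0.38039216,0.5529412
0.200000,0.38431373,0.5529412
0.200000,0.38823529,0.5529412
0.196078,0.39215686,0.5568627
0.196078,0.39607843,0.5568627
0.192157,0.40000000,0.5568627
0.192157,0.40392157,0.5568627
0.192157,0.40784314,0.5568627
0.188235,0.41176471,0.5568627
0.188235,0.41568627,0.5568627
0.184314,0.41960784,0.5568627
0.184314,0.42352941,0.5568627
0.180392,0.42745098,0.5568627
0.180392,0.43137255,0.5568627
0.180392,0.43529412,0.5568627
0.176471,0.43921569,0.5568627
0.176471,0.44313725,0.5568627
0.172549,0.44313725,0.5568627
0.172549,0.44705882,0.5568627
0.172549,0.45098039,0.5568627
0.168627,0.45490196,0.5568627
0.168627,0.45882353,0.5568627
0.164706,0.46274510,0.5568627
0.164706,0.46666667,0.5568627
0.164706,0.47058824,0.5568627
0.160784,0.47450980,0.5568627
0.160784,0.47843137,0.5568627
0.160784,0.48235294,0.5568627
0.156863,0.48627451,0.5568627
0.156863,0.49019608,0.5568627
0.152941,0.49411765,0.5568627
0.152941,0.49803922,0.5568627
0.152941,0.50196078,0.5568627
0.149020,0.50588235,0.5568627
0.149020,0.50980392,0.5568627
0.149020,0.50980392,0.5568627
0.145098,0.51372549,0.5568627
0.145098,0.51764706,0.5568627
0.145098,0.52156863,0.5568627
0.141176,0.52549020,0.5568627
0.141176,0.52941176,0.5568627
0.137255,0.53333333,0.5568627
0.137255,0.53725490,0.5568627
0.137255,0.54117647,0.5529412
0.133333,0.54509804,0.5529412
0.133333,0.54901961,0.5529412
0.133333,0.55294118,0.5529412
0.129412,0.55686275,0.5529412
0.129412,0.56078431,0.5529412
0.129412,0.56470588,0.5529412
0.129412,0.56862745,0.5490196
0.125490,0.57254902,0.5490196
0.125490,0.57254902,0.5490196
0.125490,0.57647059,0.5490196
0.121569,0.58039216,0.5490196
0.121569,0.58431373,0.5450980
0.121569,0.58823529,0.5450980
0.121569,0.59215686,0.5450980
0.121569,0.59607843,0.5450980
0.121569,0.60000000,0.5411765
0.121569,0.60392157,0.5411765
0.117647,0.60784314,0.5411765
0.117647,0.61176471,0.5372549
0.117647,0.61568627,0.5372549
0.121569,0.61960784,0.5372549
0.121569,0.62352941,0.5333333
0.121569,0.62745098,0.5333333
0.121569,0.63137255,0.5333333
0.121569,0.63137255,0.5294118
0.121569,0.63529412,0.5294118
0.125490,0.63921569,0.5254902
0.125490,0.64313725,0.5254902
0.129412,0.64705882,0.5215686
0.129412,0.65098039,0.5215686
0.133333,0.65490196,0.5215686
0.133333,0.65882353,0.5176471
0.137255,0.66274510,0.5137255
0.141176,0.66666667,0.5137255
0.145098,0.67058824,0.5098039
0.145098,0.67450980,0.5098039
0.149020,0.67843137,0.5058824
0.152941,0.67843137,0.5058824
0.156863,0.68235294,0.5019608
0.160784,0.68627451,0.4980392
0.164706,0.69019608,0.4980392
0.172549,0.69411765,0.4941176
0.176471,0.69803922,0.4901961
0.180392,0.70196078,0.4862745
0.184314,0.70588235,0.4862745
0.192157,0.70980392,0.4823529
0.196078,0.71372549,0.4784314
0.203922,0.71372549,0.4745098
0.207843,0.71764706,0.4745098
0.215686,0.72156863,0.4705882
0.219608,0.72549020,0.4666667
0.227451,0.72941176,0.4627451
0.231373,0.73333333,0.4588235
0.239216,0.73725490,0.4549020
0.247059,0.73725490,0.4509804
0.250980,0.74117647,0.4470588
0.258824,0.74509804,0.4431373
0.266667,0.74901961,0.4392157
0.274510,0.75294118,0.4352941
0.282353,0.75686275,0.4313725
0.290196,0.75686275,0.4274510
0.298039,0.76078431,0.4235294
0.305882,0.76470588,0.4196078
0.313725,0.76862745,0.4156863
0.321569,0.77254902,0.4117647
0.329412,0.77254902,0.4078431
0.337255,0.77647059,0.4039216
0.345098,0.78039216,0.3960784
0.352941,0.78431373,0.3921569
0.360784,0.78431373,0.3882353
0.368627,0.78823529,0.3843137
0.376471,0.79215686,0.3764706
0.388235,0.79607843,0.3725490
0.396078,0.79607843,0.3686275
0.403922,0.80000000,0.3607843
0.411765,0.80392157,0.3568627
0.423529,0.80392157,0.3529412
0.431373,0.80784314,0.3450980
0.439216,0.81176471,0.3411765
0.450980,0.81568627,0.3372549
0.458824,0.81568627,0.3294118
0.466667,0.81960784,0.3254902
0.478431,0.81960784,0.3176471
0.486275,0.82352941,0.3137255
0.498039,0.82745098,0.3058824
0.505882,0.82745098,0.3019608
0.517647,0.83137255,0.2941176
0.525490,0.83529412,0.2862745
0.537255,0.83529412,0.2823529
0.545098,0.83921569,0.2745098
0.556863,0.83921569,0.2705882
0.564706,0.84313725,0.2627451
0.576471,0.84313725,0.2549020
0.584314,0.84705882,0.2509804
0.596078,0.84705882,0.2431373
0.607843,0.85098039,0.2352941
0.615686,0.85098039,0.2313725
0.627451,0.85490196,0.2235294
0.635294,0.85490196,0.2156863
0.647059,0.85882353,0.2117647
0.658824,0.85882353,0.2039216
0.666667,0.86274510,0.1960784
0.678431,0.86274510,0.1882353
0.690196,0.86666667,0.1843137
0.698039,0.86666667,0.1764706
0.709804,0.87058824,0.1686275
0.721569,0.87058824,0.1607843
0.729412,0.87058824,0.1568627
0.741176,0.87450980,0.1490196
0.752941,0.87450980,0.1450980
0.760784,0.87450980,0.1372549
0.772549,0.87843137,0.1294118
0.784314,0.87843137,0.1254902
0.792157,0.88235294,0.1215686
0.803922,0.88235294,0.1137255
0.815686,0.88235294,0.1098039
0.823529,0.88627451,0.1058824
0.835294,0.88627451,0.1019608
0.847059,0.88627451,0.0980392
0.854902,0.89019608,0.0980392
0.866667,0.89019608,0.0941176
0.874510,0.89019608,0.0941176
0.886275,0.89411765,0.0941176
0.898039,0.89411765,0.0980392
0.905882,0.89411765,0.0980392
0.917647,0.89803922,0.1019608
0.925490,0.89803922,0.1058824
0.937255,0.89803922,0.1098039
0.945098,0.89803922,0.1137255
0.956863,0.90196078,0.1176471
0.964706,0.90196078,0.1254902
0.972549,0.90196078,0.1294118
0.984314,0.90588235,0.1372549
0.992157,0.90588235,0.1450980
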